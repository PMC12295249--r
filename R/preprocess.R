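#' Preprocessing configuration
#'
#' Parameters of the smoothing / resampling / baseline stage. The defaults
#' follow common practice for arterial waveforms: a 0.1 s Savitzky-Golay
#' window with polynomial order 3 (wide enough to suppress noise, short
#' enough to preserve the systolic upstroke) and a working rate of 150
#' samples per second for all downstream analysis.
#'
#' @param sg_window Savitzky-Golay window duration in seconds.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param target_rate Working sampling rate in Hz.
#' @param baseline_method `"minima"` (interpolate the per-beat minima with a
#'   shape-preserving cubic; the default, matching the definition of the
#'   baseline as the curve through the waveform bases) or `"hankel"`
#'   (low-rank trajectory-matrix reconstruction shifted through the per-beat
#'   minima).
#' @param hankel_window Embedding window for the Hankel method, as a
#'   multiple of the median RR interval.
#' @param hankel_rank Rank of the low-rank reconstruction.
#' @return A list of class `pw_preproc_config`.
#' @export
preproc_config <- function(sg_window = 0.1, sg_polyorder = 3,
                           target_rate = 150,
                           baseline_method = c("minima", "hankel"),
                           hankel_window = 1.5, hankel_rank = 2) {
  baseline_method <- match.arg(baseline_method)
  if (target_rate <= 0) {
    abort("`target_rate` must be positive.", class = "pk_invalid_parameter")
  }
  if (sg_window * target_rate < sg_polyorder + 2) {
    abort("`sg_window` x `target_rate` must be at least sg_polyorder + 2.",
          class = "pk_invalid_parameter")
  }
  structure(list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                 target_rate = target_rate,
                 baseline_method = baseline_method,
                 hankel_window = hankel_window, hankel_rank = hankel_rank),
            class = "pw_preproc_config")
}

sg_window_samples <- function(window_s, fs, polyorder) {
  n <- round(window_s * fs)
  if (n %% 2 == 0) n <- n + 1
  max(n, polyorder + 2 + (polyorder %% 2 == 1))
}

#' Savitzky-Golay smoothing of a trace
#'
#' Least-squares local-polynomial smoothing with the configured window and
#' order; edge samples are fitted on asymmetric (truncated) windows so the
#' output has the same length as the input.
#'
#' @param trace A [pw_trace()].
#' @param config A [preproc_config()].
#' @return The smoothed trace.
#' @export
pw_smooth <- function(trace, config = preproc_config()) {
  n <- sg_window_samples(config$sg_window, trace$fs, config$sg_polyorder)
  if (length(trace$samples) < n) {
    abort("trace shorter than the smoothing window.",
          class = "pk_invalid_input")
  }
  out <- trace
  out$samples <- signal::sgolayfilt(trace$samples, p = config$sg_polyorder,
                                    n = n)
  out
}

#' Resample a trace onto a uniform grid at a new rate
#'
#' Cubic-spline interpolation onto a grid spanning the same interval; the
#' duration is preserved to within one output sample. When the target rate
#' equals the native rate the samples are returned unchanged.
#'
#' @param trace A [pw_trace()].
#' @param target_rate New sampling rate in Hz.
#' @return The resampled trace.
#' @export
pw_resample <- function(trace, target_rate) {
  if (target_rate <= 0) {
    abort("`target_rate` must be positive.", class = "pk_invalid_parameter")
  }
  if (abs(target_rate - trace$fs) < 1e-9 * trace$fs) return(trace)
  tt <- trace_times(trace)
  m <- floor((length(trace$samples) - 1) / trace$fs * target_rate)
  new_t <- trace$t0 + (0:m) / target_rate
  out <- trace
  out$samples <- spline(tt, trace$samples, xout = new_t)$y
  out$fs <- target_rate
  out
}

#' Savitzky-Golay derivative of a trace
#'
#' Derivative estimated from the local least-squares polynomial (same window
#' and order as the smoother), in signal units per second. High-order
#' derivatives of sampled waveforms are meaningless from raw finite
#' differences at working rates; the polynomial estimate is what every
#' fiducial rule in the package consumes.
#'
#' @param trace A [pw_trace()].
#' @param order Derivative order: 1, 2 or 3.
#' @param config A [preproc_config()]; `sg_polyorder` must be >= `order`.
#' @return A trace of the derivative (same length and grid).
#' @export
pw_derivative <- function(trace, order, config = preproc_config()) {
  if (!order %in% 1:3) {
    abort("`order` must be 1, 2 or 3.", class = "pk_invalid_parameter")
  }
  if (order > config$sg_polyorder) {
    abort("derivative order exceeds the smoothing polynomial order.",
          class = "pk_invalid_parameter")
  }
  n <- sg_window_samples(config$sg_window, trace$fs, config$sg_polyorder)
  if (length(trace$samples) < n) {
    abort("trace shorter than the derivative window.",
          class = "pk_invalid_input")
  }
  out <- trace
  out$samples <- signal::sgolayfilt(trace$samples, p = config$sg_polyorder,
                                    n = n, m = order, ts = 1 / trace$fs)
  out$units <- paste0(trace$units, "/s^", order)
  out
}

# minimum value and position in a window preceding (and just after) an onset
beat_minima <- function(trace, onsets) {
  tt <- trace_times(trace)
  rrs <- diff(onsets)
  med_rr <- stats::median(rrs)
  purrr::map_dfr(seq_along(onsets), function(k) {
    a <- onsets[k] - 0.25 * med_rr
    b <- onsets[k] + 0.05 * med_rr
    idx <- which(tt >= a & tt <= b)
    if (!length(idx)) return(NULL)
    i <- idx[which.min(trace$samples[idx])]
    tibble(time_s = tt[i], value = trace$samples[i])
  })
}

#' Estimate the slow baseline of a pulse trace
#'
#' The baseline is the curve passing through the bases (per-beat minima,
#' the B points) of the waveform; subtracting it isolates the cardiac
#' component. Two estimators are provided: shape-preserving cubic
#' interpolation through the detected per-beat minima (`"minima"`), and a
#' Hankel (trajectory) matrix low-rank reconstruction whose slow component
#' is shifted to pass through the per-beat minima (`"hankel"`).
#'
#' @param trace A [pw_trace()] (typically smoothed and resampled).
#' @param onsets Coarse beat onset times in seconds (>= 2), e.g. from
#'   [detect_onsets()] on the smoothed raw trace.
#' @param config A [preproc_config()].
#' @return A baseline trace of equal length.
#' @export
estimate_baseline <- function(trace, onsets, config = preproc_config()) {
  if (length(onsets) < 2) {
    abort("need at least 2 onsets to estimate a baseline.",
          class = "pk_insufficient_beats")
  }
  tt <- trace_times(trace)
  knots <- beat_minima(trace, onsets)
  if (config$baseline_method == "minima") {
    base <- interp_knots(knots$time_s, knots$value, tt)
  } else {
    med_rr <- stats::median(diff(onsets))
    L <- max(8, round(config$hankel_window * med_rr * trace$fs))
    slow <- hankel_lowrank(trace$samples, L, config$hankel_rank)
    # the low-rank reconstruction keeps a residual at the cardiac
    # frequency; a moving average spanning exactly one median beat period
    # nulls that frequency and all its harmonics
    n_sm <- round(med_rr * trace$fs)
    if (n_sm %% 2 == 0) n_sm <- n_sm + 1
    if (length(slow) >= n_sm && n_sm >= 5) {
      pad <- (n_sm - 1) / 2
      padded <- c(rep(slow[1], pad), slow, rep(slow[length(slow)], pad))
      slow <- as.numeric(stats::filter(padded, rep(1 / n_sm, n_sm),
                                       sides = 2))[(pad + 1):(pad + length(slow))]
    }
    # then anchor through the per-beat minima
    idx <- pmin(pmax(round((knots$time_s - trace$t0) * trace$fs) + 1, 1),
                length(slow))
    corr <- interp_knots(knots$time_s, knots$value - slow[idx], tt)
    base <- slow + corr
  }
  out <- trace
  out$samples <- base
  out$kind <- paste0(trace$kind, "_baseline")
  out
}

# shape-preserving cubic through knots, constant beyond the end knots
interp_knots <- function(xk, yk, xout) {
  if (length(xk) < 2) return(rep(yk[1], length(xout)))
  o <- order(xk)
  xk <- xk[o]; yk <- yk[o]
  keep <- c(TRUE, diff(xk) > 1e-12)
  xk <- xk[keep]; yk <- yk[keep]
  xc <- pmin(pmax(xout, xk[1]), xk[length(xk)])
  pracma::pchip(xk, yk, xc)
}

# rank-r reconstruction from the L x K trajectory (Hankel) matrix,
# via eigendecomposition of the small L x L lag-covariance matrix
hankel_lowrank <- function(x, L, r) {
  n <- length(x)
  L <- min(L, n - 1)
  K <- n - L + 1
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- x[i:(i + K - 1)]
  S <- X %*% t(X)
  e <- eigen(S, symmetric = TRUE)
  r <- min(r, L)
  U <- e$vectors[, seq_len(r), drop = FALSE]
  Xr <- U %*% (t(U) %*% X)
  # diagonal (anti-diagonal) averaging back to a series
  out <- numeric(n)
  cnt <- numeric(n)
  for (i in seq_len(L)) {
    j <- i:(i + K - 1)
    out[j] <- out[j] + Xr[i, ]
    cnt[j] <- cnt[j] + 1
  }
  out / cnt
}

#' Subtract a baseline to extract the cardiac component
#'
#' @param trace A [pw_trace()].
#' @param baseline Baseline trace of equal length (see
#'   [estimate_baseline()]).
#' @return Trace of the cardiac component (pointwise difference).
#' @export
extract_cardiac_component <- function(trace, baseline) {
  if (length(trace$samples) != length(baseline$samples)) {
    abort("trace and baseline must have equal lengths.",
          class = "pk_invalid_input")
  }
  out <- trace
  out$samples <- trace$samples - baseline$samples
  out
}

#' Preprocess a trace or a whole recording
#'
#' Full chain: Savitzky-Golay smoothing at the native rate, resampling to
#' the working rate, and (for pulse channels) baseline removal. Baseline
#' estimation needs per-beat minima, which need beat onsets; onsets are
#' bootstrapped by running the slope-threshold detector on the smoothed
#' trace, the baseline is subtracted, and onsets are re-detected downstream
#' on the cardiac component. The ECG is smoothed and resampled with the same
#' filter but gets no baseline subtraction (only the R-peak time is ever
#' used).
#'
#' @param x A [pw_trace()] or [pw_recording()].
#' @param config A [preproc_config()].
#' @return Object of the same class, preprocessed.
#' @export
preprocess <- function(x, config = preproc_config()) UseMethod("preprocess")

#' @export
preprocess.pw_trace <- function(x, config = preproc_config()) {
  sm <- pw_resample(pw_smooth(x, config), config$target_rate)
  if (!x$kind %in% PULSE_KINDS) return(sm)
  coarse <- detect_onsets(sm, config)
  if (length(coarse) < 2) return(sm)
  base <- estimate_baseline(sm, coarse, config)
  extract_cardiac_component(sm, base)
}

#' @export
preprocess.pw_recording <- function(x, config = preproc_config()) {
  out <- x
  out$traces <- purrr::map(x$traces, preprocess, config = config)
  out
}
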