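#' Fiducial-detection configuration
#'
#' @param g_search_factor Limiting factor k for the peripheral G-point
#'   search window (tF, k tF\]; default 2.5.
#' @param min_run Minimum number of samples a third-derivative sign run
#'   must span to count as a positive/negative segment (suppresses sign
#'   chatter; default 4).
#' @param preproc A [preproc_config()] providing the derivative settings.
#' @return A list of class `pw_fiducial_config`.
#' @export
fiducial_config <- function(g_search_factor = 2.5, min_run = 4,
                            preproc = preproc_config()) {
  if (g_search_factor <= 1) {
    abort("`g_search_factor` must exceed 1.", class = "pk_invalid_parameter")
  }
  structure(list(g_search_factor = g_search_factor, min_run = min_run,
                 preproc = preproc),
            class = "pw_fiducial_config")
}

# Savitzky-Golay derivatives of a beat segment
segment_derivative <- function(seg, order, config) {
  tr <- pw_trace(seg$samples, fs = seg$fs, t0 = 0, kind = seg$kind)
  pw_derivative(tr, order, config$preproc)$samples
}

# sign runs of a derivative with runs shorter than min_run absorbed
filtered_sign_runs <- function(d, min_run) {
  s <- sign(d)
  s[s == 0] <- 1
  r <- rle(s)
  while (any(r$lengths < min_run) && length(r$lengths) > 1) {
    i <- which(r$lengths < min_run)[1]
    j <- if (i == 1) 2 else i - 1
    r$values[i] <- r$values[j]
    r <- rle(inverse.rle(r))
  }
  r
}

# first + -> - transition of d after index i0 (run-filtered)
first_pos_to_neg <- function(d, i0, min_run) {
  r <- filtered_sign_runs(d, min_run)
  starts <- cumsum(c(1, head(r$lengths, -1)))
  for (q in seq_along(r$values)[-1]) {
    if (r$values[q] < 0 && r$values[q - 1] > 0 && starts[q] > i0 + 1) {
      return(starts[q] - 1L)
    }
  }
  NA_integer_
}

# first contiguous block of d > 0 at indices > i0 (run-filtered so that
# sign chatter shorter than min_run cannot masquerade as a segment)
first_positive_block <- function(d, i0, min_run = 1) {
  r <- if (min_run > 1) filtered_sign_runs(d, min_run) else {
    s <- sign(d); s[s == 0] <- 1; rle(s)
  }
  starts <- cumsum(c(1, head(r$lengths, -1)))
  ends <- cumsum(r$lengths)
  for (q in seq_along(r$values)) {
    if (r$values[q] > 0 && ends[q] > i0) {
      return(max(starts[q], i0 + 1):ends[q])
    }
  }
  integer(0)
}

# first index >= i0 where a (run-filtered) negative run of d begins
first_negative_start <- function(d, i0, min_run) {
  r <- filtered_sign_runs(d, min_run)
  starts <- cumsum(c(1, head(r$lengths, -1)))
  for (q in seq_along(r$values)) {
    if (r$values[q] < 0 && starts[q] >= i0) return(starts[q])
  }
  NA_integer_
}

fiducial_tibble <- function(idx, t, x, kind) {
  tibble(
    point = names(idx),
    time_s = unname(ifelse(is.na(idx), NA_real_,
                           t[replace(idx, is.na(idx), 1L)])),
    amplitude = unname(ifelse(is.na(idx), NA_real_,
                              x[replace(idx, is.na(idx), 1L)])),
    detected = unname(!is.na(idx)),
    channel = kind
  )
}

#' Locate fiducial points on a peripheral (EBI/RAP) beat
#'
#' Rules: B is the first sample of the period (onset, tB = 0); C the
#' maximum of the first derivative between B and D (maximum upstroke
#' slope); D the global sample maximum (peak); F the first
#' positive-to-negative transition of the third derivative after D (onset
#' of reduced ejection); G the most negative third-derivative excursion in
#' (tF, k tF\] (dicrotic notch onset). All derivatives are Savitzky-Golay
#' polynomial derivatives; ties break to the earliest sample; points whose
#' defining condition has no solution are flagged undetectable, never
#' fabricated.
#'
#' @param seg A `pw_segment` of at least 0.3 s.
#' @param config A [fiducial_config()].
#' @return Tibble with columns `point`, `time_s` (period-local), `amplitude`,
#'   `detected`, `channel`.
#' @export
detect_peripheral_fiducials <- function(seg, config = fiducial_config()) {
  x <- seg$samples
  if (length(x) / seg$fs < 0.3) {
    abort("period shorter than 0.3 s.", class = "pk_invalid_input")
  }
  t <- (seq_along(x) - 1) / seg$fs
  d1 <- segment_derivative(seg, 1, config)
  d3 <- segment_derivative(seg, 3, config)
  n <- length(x)
  iD <- which.max(x)
  iC <- which.max(replace(d1, seq_len(n) > iD, -Inf))
  iF <- first_pos_to_neg(d3, iD, config$min_run)
  iG <- NA_integer_
  if (!is.na(iF)) {
    win <- which(t > t[iF] &
                   t <= min(config$g_search_factor * t[iF], t[n]))
    if (length(win)) iG <- win[which.min(d3[win])]
  }
  fiducial_tibble(c(B = 1L, C = iC, D = iD, F = iF, G = iG), t, x, seg$kind)
}

#' Locate fiducial points on a central aortic pressure beat
#'
#' Rules: B is the first sample (tB = 0); C the first-derivative maximum
#' before the pressure maximum; F the global sample maximum (systolic
#' pressure peak); D the third-derivative maximum within the first positive
#' third-derivative segment after C, restricted to \[tC, 0.95 tF\] (the
#' inflection where ventricular ejection deceleration completes); G the
#' start of the first negative third-derivative segment after the
#' first-derivative minimum, searched up to halfway between that minimum
#' and the end of the period (dicrotic notch onset). The ordering
#' B < C < D < F < G is enforced; violations flag the offending point.
#'
#' @inheritParams detect_peripheral_fiducials
#' @return Tibble as in [detect_peripheral_fiducials()].
#' @export
detect_cap_fiducials <- function(seg, config = fiducial_config()) {
  x <- seg$samples
  if (length(x) / seg$fs < 0.3) {
    abort("period shorter than 0.3 s.", class = "pk_invalid_input")
  }
  t <- (seq_along(x) - 1) / seg$fs
  d1 <- segment_derivative(seg, 1, config)
  d3 <- segment_derivative(seg, 3, config)
  n <- length(x)
  iF <- which.max(x)
  iC <- which.max(replace(d1, seq_len(n) > iF, -Inf))
  win <- which(seq_len(n) > iC & t <= 0.95 * t[iF])
  iD <- if (length(win) && max(d3[win]) > 0) win[which.max(d3[win])] else NA_integer_
  imin <- which.min(d1)
  lim <- t[imin] + (t[n] - t[imin]) / 2
  iG <- first_negative_start(d3, imin, config$min_run)
  if (!is.na(iG) && t[iG] > lim) iG <- NA_integer_
  if (!is.na(iG) && iG <= iF) iG <- NA_integer_
  fiducial_tibble(c(B = 1L, C = iC, D = iD, F = iF, G = iG), t, x, seg$kind)
}

#' Detect fiducials on any beat segment by channel kind
#'
#' Dispatches to the peripheral or central rules according to the segment's
#' channel kind.
#'
#' @inheritParams detect_peripheral_fiducials
#' @export
detect_fiducials <- function(seg, config = fiducial_config()) {
  if (seg$kind == "cap") detect_cap_fiducials(seg, config)
  else detect_peripheral_fiducials(seg, config)
}

#' Locate the R peak in an ECG segment
#'
#' The R time is the time of the maximum sample (or of the maximum
#' deviation from the segment median under `polarity = "auto"`, which makes
#' the result invariant to lead inversion), refined by parabolic
#' interpolation through the three samples around the peak. Each segment is
#' expected to contain exactly one R wave by construction of the ECG
#' segmentation.
#'
#' @param seg An ECG `pw_segment`.
#' @param polarity `"auto"`, `"+"` or `"-"`.
#' @return R-peak time in seconds (absolute).
#' @export
detect_r_peak <- function(seg, polarity = c("auto", "+", "-")) {
  polarity <- match.arg(polarity)
  x <- seg$samples
  if (!length(x)) abort("empty segment.", class = "pk_invalid_input")
  if (diff(range(x)) < 1e-12) {
    abort("flat ECG segment: no R peak.", class = "pk_no_peak")
  }
  y <- switch(polarity,
              "auto" = abs(x - stats::median(x)),
              "+" = x,
              "-" = -x)
  i <- which.max(y)
  # parabolic vertex through the neighbouring samples (sub-sample refinement)
  off <- 0
  if (i > 1 && i < length(x)) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (abs(denom) > 1e-30) {
      off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
      if (!is.finite(off) || abs(off) > 0.5) off <- 0
    }
  }
  seg$t0 + (i - 1 + off) / seg$fs
}

#' Timing intervals derived from a fiducial set
#'
#' Systolic upstroke time `Tu` (onset to peak: D for peripheral beats, F
#' for central), inflection time `T1` (onset to D, central beats),
#' ejection duration `TED` and end-systole time `Ted` (onset to the
#' dicrotic notch G), and the reflected-wave systolic duration
#' `T2 = TED - T1`. Intervals whose defining points were not detected are
#' returned as `NA`.
#'
#' @param fiducials Tibble from a fiducial detector.
#' @return One-row tibble with columns `Tu`, `T1`, `Ted`, `T2`, `TED` (s).
#' @export
compute_intervals <- function(fiducials) {
  tm <- setNames(fiducials$time_s, fiducials$point)
  get_t <- function(p) if (p %in% names(tm)) tm[[p]] else NA_real_
  central <- isTRUE(fiducials$channel[1] == "cap")
  tB <- get_t("B")
  tu <- if (central) get_t("F") - tB else get_t("D") - tB
  t1 <- if (central) get_t("D") - tB else NA_real_
  ted <- get_t("G") - tB
  tibble(Tu = tu, T1 = t1, Ted = ted,
         T2 = if (central) ted - t1 else NA_real_, TED = ted)
}
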