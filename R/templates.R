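#' @section Pulse templates:
#' Single-beat waveforms are synthesized as a sum of smooth components in
#' beat-relative time u = t / period, u in \[0, 1):
#' a gamma-kernel systolic wave with a sharp foot at u = 0, a delayed
#' gamma-kernel diastolic (reflected) wave, and a localized negative
#' raised-cosine notch component between them (the dicrotic incisure).
#' A cosine fade-out window forces the waveform to return smoothly to its
#' minimum (zero) before the next beat, so a concatenated train is
#' continuous. The parameters below were chosen so that the onset, maximum
#' upstroke slope, peak/inflection, systolic maximum and notch landmarks
#' exist, are strictly ordered, and the third-derivative detection rules
#' have unique, numerically stable solutions across periods of 0.6-1.2 s.
#' @name pulse-templates
#' @keywords internal
NULL

# normalized gamma kernel: zero for x <= 0, peak 1 at x = p*th (x = (u-on)/th)
gamma_bump <- function(u, onset, p, th) {
  x <- (u - onset) / th
  v <- numeric(length(u))
  pos <- x > 0
  v[pos] <- (x[pos] / p)^p * exp(p - x[pos])
  v
}

# symmetric cos^4 bump of half-width w centered at c (compact support)
cosine_bump <- function(u, center, w, amp) {
  v <- numeric(length(u))
  s <- abs(u - center) / w
  inside <- s < 1
  v[inside] <- cos(pi * s[inside] / 2)^4
  amp * v
}

# smooth fade to exactly zero on [u0, 1]
fade_window <- function(u, u0 = 0.85) {
  v <- rep(1, length(u))
  late <- u > u0
  v[late] <- cos(pi * (u[late] - u0) / (2 * (1 - u0)))^4
  v
}

# Per-channel shape in relative time. The foot exponent of the systolic
# kernel controls how fast the upstroke slope builds; it is calibrated so
# that the slope-threshold onset detector locates the beat start to within
# a few milliseconds at typical heart rates.
TEMPLATE_PARAMS <- list(
  ebi = list(
    gam = list(c(on = 0, p = 2.8, th = 0.15 / 2.8, amp = 1.00),      # systolic
               c(on = 0.22, p = 3, th = 0.13, amp = 0.36)),          # diastolic
    cos = list(c(c = 0.30, w = 0.090, amp = 0.050),                  # inflection
               c(c = 0.43, w = 0.090, amp = -0.060))                 # notch
  ),
  rap = list(
    gam = list(c(on = 0, p = 3.0, th = 0.14 / 3.0, amp = 1.00),
               c(on = 0.24, p = 3, th = 0.14, amp = 0.30)),
    cos = list(c(c = 0.32, w = 0.110, amp = 0.050),                  # inflection
               c(c = 0.44, w = 0.100, amp = -0.055))                 # notch
  ),
  cap = list(
    gam = list(c(on = 0, p = 3.05, th = 0.13 / 3.05, amp = 0.72),    # upstroke
               c(on = 0.02, p = 5, th = 0.065, amp = 0.95)),         # late systolic
    cos = list(c(c = 0.14, w = 0.080, amp = 0.060),                  # reflected-wave
                                                                     # inflection
               c(c = 0.47, w = 0.090, amp = -0.060))                 # notch
  )
)

pulse_shape <- function(kind, u) {
  p <- TEMPLATE_PARAMS[[kind]]
  if (is.null(p)) {
    abort(sprintf("unknown pulse channel kind '%s'.", kind),
          class = "pk_invalid_parameter")
  }
  v <- numeric(length(u))
  for (g in p$gam) v <- v + g[["amp"]] * gamma_bump(u, g[["on"]], g[["p"]], g[["th"]])
  for (cc in p$cos) v <- v + cosine_bump(u, cc[["c"]], cc[["w"]], cc[["amp"]])
  v * fade_window(u)
}

#' Generate a noise-free single-beat pulse template with ground truth
#'
#' Returns one beat of the synthetic waveform for a pulse channel together
#' with its ground-truth fiducial points. The fiducials are always computed
#' by brute-force derivative analysis on the dense grid itself (never read
#' off the template parameters), so they form an oracle that is independent
#' of the package's Savitzky-Golay based detectors.
#'
#' @param kind `"ebi"`, `"rap"` (peripheral morphology) or `"cap"` (central
#'   aortic morphology).
#' @param period Beat duration in seconds, in \[0.4, 2.0\].
#' @param grid_rate Dense grid rate in Hz (>= 1000; default 10000).
#' @return A list with elements `trace` (a [pw_trace()] starting at t = 0)
#'   and `fiducials` (a tibble with columns `point`, `time_s`, `amplitude`,
#'   `detected`). The waveform starts and ends at its minimum value (zero).
#' @examples
#' tpl <- generate_pulse_template("ebi", period = 1)
#' tpl$fiducials
#' @export
generate_pulse_template <- function(kind, period, grid_rate = 10000) {
  if (!is.numeric(period) || length(period) != 1 ||
      period < 0.4 || period > 2.0) {
    abort("`period` must lie in [0.4, 2.0] s.", class = "pk_invalid_parameter")
  }
  if (grid_rate < 1000) {
    abort("`grid_rate` must be >= 1000 Hz.", class = "pk_invalid_parameter")
  }
  t <- seq(0, period - 1 / grid_rate, by = 1 / grid_rate)
  x <- pulse_shape(kind, t / period)
  fid <- oracle_fiducials(x, grid_rate, kind)
  list(trace = pw_trace(x, fs = grid_rate, t0 = 0, kind = kind),
       fiducials = fid)
}

#' Brute-force fiducial oracle on a dense grid
#'
#' Locates the fiducial points of a single noise-free beat by direct
#' finite-difference derivative analysis on the sampling grid. Intended for
#' densely sampled (>= 1 kHz) smooth waveforms, where finite differences are
#' essentially exact; it serves as the reference against which the
#' Savitzky-Golay detectors ([detect_peripheral_fiducials()],
#' [detect_cap_fiducials()]) are validated.
#'
#' The rules mirror the detector definitions: for peripheral (EBI/RAP)
#' beats, B is the first sample, C the maximum of the first derivative
#' before the global peak D, F the first positive-to-negative transition of
#' the third derivative after D, and G the most negative third-derivative
#' excursion in (tF, k tF\]. For central (CAP) beats, F is the global
#' maximum, C the first-derivative maximum before it, D the third-derivative
#' maximum on \[tC, 0.95 tF\], and G the start of the first negative
#' third-derivative segment after the first-derivative minimum, within half
#' the remaining beat.
#'
#' @param x Numeric samples of one beat (beat-local, first sample = onset).
#' @param fs Sampling rate in Hz.
#' @param kind Channel kind (`"ebi"`, `"rap"`, `"cap"`).
#' @param k Search-limit factor for the peripheral G point (default 2.5).
#' @return Tibble with columns `point`, `time_s` (beat-local, tB = 0),
#'   `amplitude`, `detected`.
#' @export
oracle_fiducials <- function(x, fs, kind, k = 2.5) {
  dt <- 1 / fs
  t <- (seq_along(x) - 1) * dt
  d1 <- c(NA, diff(x)) / dt
  d3 <- x
  for (i in 1:3) d3 <- c(NA, diff(d3)) / dt
  n <- length(x)

  if (kind %in% c("ebi", "rap")) {
    iD <- which.max(x)
    iC <- which.max(replace(d1, seq_len(n) > iD, -Inf))
    iF <- NA_integer_
    if (iD + 1 < n) {
      for (i in (iD + 1):(n - 1)) {
        if (!is.na(d3[i]) && d3[i] > 0 && !is.na(d3[i + 1]) && d3[i + 1] <= 0) {
          iF <- i; break
        }
      }
    }
    iG <- NA_integer_
    if (!is.na(iF)) {
      win <- which(t > t[iF] & t <= min(k * t[iF], t[n]))
      if (length(win)) iG <- win[which.min(d3[win])]
    }
    idx <- c(B = 1L, C = iC, D = iD, F = iF, G = iG)
  } else if (kind == "cap") {
    iF <- which.max(x)
    iC <- which.max(replace(d1, seq_len(n) > iF, -Inf))
    win <- which(seq_len(n) > iC & t <= 0.95 * t[iF] & !is.na(d3))
    iD <- if (length(win) && max(d3[win]) > 0) win[which.max(d3[win])] else NA_integer_
    imin <- which.min(d1)
    lim <- t[imin] + (t[n] - t[imin]) / 2
    iG <- NA_integer_
    i <- max(imin, 2)
    while (i <= n) {
      if (!is.na(d3[i]) && d3[i] < 0 && !is.na(d3[i - 1]) && d3[i - 1] >= 0) {
        iG <- i; break
      }
      i <- i + 1
    }
    if (!is.na(iG) && t[iG] > lim) iG <- NA_integer_
    idx <- c(B = 1L, C = iC, D = iD, F = iF, G = iG)
  } else {
    abort(sprintf("no fiducial rules for kind '%s'.", kind),
          class = "pk_invalid_parameter")
  }

  tibble(
    point = names(idx),
    time_s = unname(ifelse(is.na(idx), NA_real_,
                           t[replace(idx, is.na(idx), 1L)])),
    amplitude = unname(ifelse(is.na(idx), NA_real_,
                              x[replace(idx, is.na(idx), 1L)])),
    detected = unname(!is.na(idx))
  )
}
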