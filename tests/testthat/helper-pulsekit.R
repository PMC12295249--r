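# Shared helpers for the test suite. Fixtures are generated in code; no
# binary data is stored.

# a beat segment from raw samples
make_segment <- function(x, fs, kind = "ebi", t0 = 0, beat = 1L) {
  pulsekit:::new_segment(x, fs, t0, t0, beat, kind)
}

# Independent brute-force fiducial analysis used as a test oracle. This is
# deliberately written from the rule definitions with plain finite
# differences, separate from both the package detector and
# oracle_fiducials().
bruteforce_peripheral <- function(x, fs, k = 2.5) {
  dt <- 1 / fs
  t <- (seq_along(x) - 1) * dt
  d1 <- c(NA, diff(x)) / dt
  d3 <- c(NA, diff(c(NA, diff(c(NA, diff(x)))))) / dt^3
  iD <- which.max(x)
  iF <- NA
  for (i in (iD + 1):(length(x) - 1)) {
    if (!is.na(d3[i]) && d3[i] > 0 && !is.na(d3[i + 1]) && d3[i + 1] <= 0) {
      iF <- i
      break
    }
  }
  iG <- NA
  if (!is.na(iF)) {
    win <- which(t > t[iF] & t <= min(k * t[iF], t[length(t)]))
    if (length(win)) iG <- win[which.min(d3[win])]
  }
  list(tD = t[iD], tF = if (is.na(iF)) NA else t[iF],
       tG = if (is.na(iG)) NA else t[iG])
}

# Independent mid-rank Spearman coefficient: explicit covariance formula on
# average ranks, no call into the package or into cor() on ranks.
midrank_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exhaustive two-sided rank-sum p-value by enumerating group-label
# assignments (test-local implementation).
enumerate_ranksum_p <- function(v1, v2) {
  n1 <- length(v1)
  n <- n1 + length(v2)
  r <- rank(c(v1, v2))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  wall <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(wall - mu) >= abs(w - mu) - 1e-9)
}

# map pipeline beat ids (from channel segments) to generator beat indices
truth_beat_of <- function(segs, truth, channel, tol = 0.25) {
  tru <- truth$onsets[truth$onsets$channel == channel, ]
  vapply(segs, function(s) {
    d <- abs(tru$time_s - s$onset_time)
    if (min(d) < tol) tru$beat[which.min(d)] else NA_integer_
  }, integer(1))
}

# noise levels giving SNR 20 dB against the default template amplitudes
# (template RMS is about one third of the pulse amplitude)
snr20_noise <- c(ecg = 0.02, cap = 1.3, rap = 1.5, ebi = 0.033)
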