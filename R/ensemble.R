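#' Detect beat onsets by the slope-threshold rule
#'
#' The beat onset (B point) is the time at which the signal's first
#' derivative rises above the threshold `L_B = 0.15 * max(S')`, where
#' `max(S')` is the global maximum of the first derivative over the trace.
#' Upward crossings closer than the refractory interval to the previous
#' accepted onset are ignored; crossing times are refined by linear
#' interpolation between the bracketing samples.
#'
#' @param trace A cardiac-component [pw_trace()] of at least 2 s.
#' @param config A [preproc_config()] (derivative settings).
#' @param refractory Minimum spacing between onsets in seconds
#'   (default 0.4 s, i.e. a 150 bpm ceiling for sinus rhythm).
#' @return Numeric vector of absolute onset times (possibly empty), with the
#'   threshold in attribute `"threshold"`.
#' @export
detect_onsets <- function(trace, config = preproc_config(),
                          refractory = 0.4) {
  if ((length(trace$samples) - 1) / trace$fs < 2) {
    abort("trace must cover at least 2 s.", class = "pk_invalid_input")
  }
  d1 <- pw_derivative(trace, 1, config)$samples
  smax <- max(d1)
  # a flat trace yields only numerical-noise derivatives; no threshold exists
  if (!is.finite(smax) ||
      smax <= 1e-10 * max(abs(trace$samples), 1) * trace$fs / 100) {
    return(structure(numeric(0), threshold = NA_real_))
  }
  lb <- 0.15 * smax
  tt <- trace_times(trace)
  i <- which(d1[-1] >= lb & d1[-length(d1)] < lb)
  if (!length(i)) return(structure(numeric(0), threshold = lb))
  cross <- tt[i] + (lb - d1[i]) / (d1[i + 1] - d1[i]) / trace$fs
  kept <- cross[1]
  for (x in cross[-1]) {
    if (x - kept[length(kept)] >= refractory) kept <- c(kept, x)
  }
  structure(kept, threshold = lb)
}

new_segment <- function(samples, fs, t0, onset_time, beat, kind) {
  structure(list(samples = samples, fs = fs, t0 = t0,
                 onset_time = onset_time, beat = beat, kind = kind),
            class = "pw_segment")
}

#' @export
print.pw_segment <- function(x, ...) {
  cat(sprintf("<pw_segment> %s beat %d @ %.3f s (%d samples, %g Hz)\n",
              x$kind, x$beat, x$onset_time, length(x$samples), x$fs))
  invisible(x)
}

#' Cut a trace into cardiac periods at detected onsets
#'
#' Beat i covers the half-open window \[onset_i, onset_(i+1)); the last
#' onset opens no beat. Beats with durations outside \[0.3, 2.5\] s are
#' dropped and logged (attribute `"removed"`).
#'
#' @param trace A [pw_trace()].
#' @param onsets Onset times from [detect_onsets()] (>= 2).
#' @param duration_bounds Admissible beat durations in seconds.
#' @return List of `pw_segment` objects with sequential beat indices.
#' @export
segment_periods <- function(trace, onsets, duration_bounds = c(0.3, 2.5)) {
  if (length(onsets) < 2) {
    abort("need at least 2 onsets to cut periods.",
          class = "pk_insufficient_beats")
  }
  tt <- trace_times(trace)
  segs <- list()
  removed <- tibble(beat = integer(), reason = character())
  for (k in seq_len(length(onsets) - 1)) {
    dur <- onsets[k + 1] - onsets[k]
    if (dur < duration_bounds[1] || dur > duration_bounds[2]) {
      removed <- bind_rows(removed,
                           tibble(beat = k, reason = "duration_out_of_bounds"))
      next
    }
    idx <- which(tt >= onsets[k] & tt < onsets[k + 1])
    if (length(idx) < 2) {
      removed <- bind_rows(removed, tibble(beat = k, reason = "empty_window"))
      next
    }
    segs[[length(segs) + 1]] <-
      new_segment(trace$samples[idx], trace$fs, tt[idx[1]], onsets[k], k,
                  trace$kind)
  }
  structure(segs, removed = removed)
}

#' Select ECG segments matched to impedance beats
#'
#' For each pulse beat window \[a, b) the ECG segment \[a - shift, b - shift)
#' is extracted with the same beat index; the default 300 ms back-shift
#' captures the whole ECG period, including the R peak that precedes the
#' peripheral pulse onset by the pulse arrival time. Windows falling outside
#' the ECG extent are dropped and logged.
#'
#' @param ecg ECG [pw_trace()] (preprocessed).
#' @param beats List of `pw_segment` pulse beats (typically EBI).
#' @param shift Back-shift in seconds (default 0.3).
#' @return List of ECG `pw_segment`s with attribute `"removed"`.
#' @export
select_ecg_segments <- function(ecg, beats, shift = 0.3) {
  tt <- trace_times(ecg)
  segs <- list()
  removed <- tibble(beat = integer(), reason = character())
  for (sg in beats) {
    a <- sg$onset_time - shift
    b <- sg$onset_time + length(sg$samples) / sg$fs - shift
    if (a < tt[1] - 1e-9 || b > tt[length(tt)] + 1e-9) {
      removed <- bind_rows(removed,
                           tibble(beat = sg$beat, reason = "outside_ecg"))
      next
    }
    idx <- which(tt >= a & tt < b)
    segs[[length(segs) + 1]] <-
      new_segment(ecg$samples[idx], ecg$fs, tt[idx[1]], a, sg$beat, "ecg")
  }
  structure(segs, removed = removed)
}

#' Synchronize per-channel beat collections
#'
#' Aligns beat indices across channels by onset proximity to a reference
#' channel (arrival-time offsets between channels are small compared to an
#' RR interval) and keeps only beat indices present in every channel;
#' periods found in only some channels are excluded and logged.
#'
#' @param channels Named list: channel kind -> list of `pw_segment`s.
#' @param reference Reference channel for index alignment (default `"ebi"`
#'   if present, else the first channel). The ECG channel, whose segments
#'   are constructed from the reference beats by [select_ecg_segments()],
#'   keeps its indices.
#' @return A `pw_sync` object: `channels` (aligned, common beat-index set)
#'   and `removed` (provenance tibble).
#' @export
synchronize <- function(channels, reference = NULL) {
  if (!length(channels)) {
    abort("need at least one channel.", class = "pk_insufficient_beats")
  }
  reference <- reference %||%
    (if ("ebi" %in% names(channels)) "ebi" else names(channels)[1])
  removed <- tibble(channel = character(), beat = integer(),
                    stage = character(), reason = character(),
                    score = numeric())
  ref <- channels[[reference]]
  if (!length(ref)) {
    abort("reference channel has no beats.", class = "pk_insufficient_beats")
  }
  ref_onsets <- map_dbl(ref, "onset_time")
  ref_ids <- vapply(ref, function(s) s$beat, integer(1))
  med_rr <- if (length(ref_onsets) > 1) stats::median(diff(ref_onsets)) else 1
  aligned <- list()
  for (ch in names(channels)) {
    segs <- channels[[ch]]
    if (ch %in% c(reference, "ecg")) {
      aligned[[ch]] <- segs
      next
    }
    out <- list()
    used <- integer(0)
    for (sg in segs) {
      d <- abs(ref_onsets - sg$onset_time)
      j <- which.min(d)
      if (d[j] > 0.45 * med_rr || ref_ids[j] %in% used) {
        removed <- bind_rows(removed,
                             tibble(channel = ch, beat = sg$beat,
                                    stage = "synchronize",
                                    reason = "no_matching_reference_beat",
                                    score = NA_real_))
        next
      }
      sg$beat <- ref_ids[j]
      used <- c(used, ref_ids[j])
      out[[length(out) + 1]] <- sg
    }
    aligned[[ch]] <- out
  }
  ids <- purrr::map(aligned, ~ vapply(.x, function(s) s$beat, integer(1)))
  common <- Reduce(intersect, ids)
  if (!length(common)) {
    abort("no beat is present in every channel.",
          class = "pk_insufficient_beats")
  }
  for (ch in names(aligned)) {
    keep <- ids[[ch]] %in% common
    drop_ids <- ids[[ch]][!keep]
    if (length(drop_ids)) {
      removed <- bind_rows(removed,
                           tibble(channel = ch, beat = drop_ids,
                                  stage = "synchronize",
                                  reason = "absent_in_other_channel",
                                  score = NA_real_))
    }
    aligned[[ch]] <- aligned[[ch]][keep]
    ord <- order(vapply(aligned[[ch]], function(s) s$beat, integer(1)))
    aligned[[ch]] <- aligned[[ch]][ord]
  }
  structure(list(channels = aligned, removed = removed), class = "pw_sync")
}

#' @export
print.pw_sync <- function(x, ...) {
  nb <- if (length(x$channels)) length(x$channels[[1]]) else 0
  cat(sprintf("<pw_sync> %d channel(s) x %d synchronized beat(s); %d removal(s) logged\n",
              length(x$channels), nb, nrow(x$removed)))
  invisible(x)
}

#' Beat indices shared by all channels of an ensemble
#' @param sync A `pw_sync`.
#' @return Sorted integer vector of beat indices.
#' @export
sync_beat_ids <- function(sync) {
  if (!length(sync$channels)) return(integer(0))
  sort(vapply(sync$channels[[1]], function(s) s$beat, integer(1)))
}

#' Outlier-rejection configuration
#'
#' @param length_band Admissible beat lengths as multiples of the median
#'   length (default 0.6-1.4; beats outside are "very short/long").
#' @param contamination Upper bound on the fraction a score-based step may
#'   drop (default 0.1).
#' @param pca_var Fraction of variance the retained principal components
#'   must explain (component count is capped at n_beats - 1).
#' @param degenerate_guard_tol If all pairwise beat RMS differences are
#'   below this fraction of the median beat RMS, the score-based steps drop
#'   nothing (the ensemble is already clean).
#' @param gate_pca,gate_copod Multiples of the median step score a beat's
#'   score must exceed before the step may drop it. A genuinely corrupted
#'   beat scores orders of magnitude above the ensemble median, while
#'   fraction-based trimming alone would always sacrifice clean beats; the
#'   gates generalize the degenerate guard to noisy but clean ensembles.
#' @return A list of class `pw_outlier_config`.
#' @export
outlier_config <- function(length_band = c(0.6, 1.4), contamination = 0.1,
                           pca_var = 0.9, degenerate_guard_tol = 0.02,
                           gate_pca = 1000, gate_copod = 4) {
  if (!(length_band[1] > 0 && length_band[1] < 1 && length_band[2] > 1)) {
    abort("`length_band` must satisfy 0 < low < 1 < high.",
          class = "pk_invalid_parameter")
  }
  if (contamination <= 0 || contamination >= 0.5) {
    abort("`contamination` must lie in (0, 0.5).",
          class = "pk_invalid_parameter")
  }
  structure(list(length_band = length_band, contamination = contamination,
                 pca_var = pca_var,
                 degenerate_guard_tol = degenerate_guard_tol,
                 gate_pca = gate_pca, gate_copod = gate_copod),
            class = "pw_outlier_config")
}

# equal-length beat matrix (rows = beats) by index-grid spline resampling
beat_matrix <- function(segs, L = NULL) {
  lens <- vapply(segs, function(s) length(s$samples), integer(1))
  L <- L %||% max(2L, round(stats::median(lens)))
  M <- matrix(0, length(segs), L)
  for (i in seq_along(segs)) {
    x <- segs[[i]]$samples
    if (length(x) == L) {
      M[i, ] <- x
    } else {
      M[i, ] <- spline(seq(0, 1, length.out = length(x)), x,
                       xout = seq(0, 1, length.out = L))$y
    }
  }
  M
}

# Reconstruction error after projection on the leading principal
# components. The basis is fitted on the half of the beats closest to the
# column-median beat: a basis fitted on all beats absorbs any repeated
# corruption pattern into the principal subspace (masking), which would
# let grouped artifacts reconstruct themselves; the robust fit keeps the
# subspace describing the clean beat-to-beat variation only. All beats are
# then scored against that basis.
pca_scores <- function(M, var_explained = 0.9) {
  med <- apply(M, 2, stats::median)
  d <- sqrt(rowMeans(sweep(M, 2, med)^2))
  fit <- which(d <= stats::quantile(d, 0.5) + 1e-300)
  if (length(fit) < 2) fit <- seq_len(nrow(M))
  mu <- colMeans(M[fit, , drop = FALSE])
  X <- sweep(M, 2, mu)
  Xf <- X[fit, , drop = FALSE]
  tot <- sum(Xf^2)
  if (tot < 1e-20 * max(sum(X^2), 1e-300)) {
    return(rowSums(X^2))
  }
  pc <- stats::prcomp(Xf, center = FALSE)
  v <- pc$sdev^2
  q <- which(cumsum(v) / sum(v) >= var_explained)[1]
  q <- min(q, length(fit) - 1)
  U <- pc$rotation[, seq_len(q), drop = FALSE]
  recon <- (X %*% U) %*% t(U)
  rowSums((X - recon)^2)
}

# empirical-copula tail-probability outlier score (COPOD-style):
# per dimension, left/right empirical tail probabilities; aggregate the
# negative log tails, with a skewness-directed variant; score = max of the
# left, right and skewness-corrected aggregates
copod_scores <- function(M) {
  n <- nrow(M); d <- ncol(M)
  pl <- apply(M, 2, function(col) rank(col, ties.method = "max") / n)
  pr <- apply(-M, 2, function(col) rank(col, ties.method = "max") / n)
  skew <- apply(M, 2, function(col) {
    s <- sd(col)
    if (s < 1e-12) 0 else mean(((col - mean(col)) / s)^3)
  })
  ol <- -log(pl); or <- -log(pr)
  os <- ol
  os[, skew >= 0] <- or[, skew >= 0]
  pmax(rowSums(ol), rowSums(or), rowSums(os))
}

rms <- function(x) sqrt(mean(x^2))

# TRUE when all pairwise beat differences are negligible
is_degenerate <- function(M, tol) {
  r <- apply(M, 1, rms)
  med <- stats::median(r)
  if (med < 1e-300) return(TRUE)
  for (i in seq_len(nrow(M) - 1)) {
    for (j in (i + 1):nrow(M)) {
      if (rms(M[i, ] - M[j, ]) >= tol * med) return(FALSE)
    }
  }
  TRUE
}

# indices to drop: in the top `max_drop` scores AND far above the median
gated_top <- function(scores, max_drop, gate_ratio) {
  if (max_drop < 1) return(integer(0))
  med <- max(stats::median(scores), 1e-300)
  cand <- order(scores, decreasing = TRUE)[seq_len(max_drop)]
  cand[scores[cand] > gate_ratio * med]
}

#' Three-step outlier rejection on a synchronized ensemble
#'
#' Applied sequentially per channel: (1) beats whose length falls outside
#' `length_band` times the median length are excluded; (2) a PCA detector
#' scores beats by reconstruction error after projection onto the leading
#' principal components of the (temporarily length-normalized) beat matrix;
#' (3) an empirical-copula tail-probability detector scores the survivors.
#' In steps 2-3 a beat is dropped only if it ranks in the top
#' `contamination` fraction *and* its score exceeds the step's gate
#' (a multiple of the median score); if all beats are indistinguishable (degenerate
#' guard) the score steps drop nothing. Finally only beat indices surviving
#' in every channel are kept, and every removal is logged with its step and
#' score.
#'
#' @param sync A `pw_sync` from [synchronize()].
#' @param config An [outlier_config()].
#' @return A filtered `pw_sync`; provenance in `$removed`.
#' @export
remove_outliers <- function(sync, config = outlier_config()) {
  removed <- sync$removed
  chans <- sync$channels
  for (ch in names(chans)) {
    segs <- chans[[ch]]
    if (!length(segs)) next
    lens <- vapply(segs, function(s) length(s$samples), integer(1))
    med_len <- stats::median(lens)
    bad <- which(lens < config$length_band[1] * med_len |
                   lens > config$length_band[2] * med_len)
    if (length(bad)) {
      removed <- bind_rows(removed, tibble(
        channel = ch,
        beat = vapply(segs[bad], function(s) s$beat, integer(1)),
        stage = "length_filter", reason = "length_out_of_band",
        score = lens[bad] / med_len))
      segs <- segs[-bad]
    }
    if (length(segs) >= 4) {
      M <- beat_matrix(segs)
      if (!is_degenerate(M, config$degenerate_guard_tol)) {
        sc <- pca_scores(M, config$pca_var)
        drop <- gated_top(sc, ceiling(config$contamination * length(segs)),
                          config$gate_pca)
        if (length(drop)) {
          removed <- bind_rows(removed, tibble(
            channel = ch,
            beat = vapply(segs[drop], function(s) s$beat, integer(1)),
            stage = "pca", reason = "reconstruction_error",
            score = sc[drop]))
          segs <- segs[-drop]
        }
      }
      if (length(segs) >= 4) {
        M <- beat_matrix(segs)
        if (!is_degenerate(M, config$degenerate_guard_tol)) {
          sc <- copod_scores(M)
          drop <- gated_top(sc, ceiling(config$contamination * length(segs)),
                            config$gate_copod)
          if (length(drop)) {
            removed <- bind_rows(removed, tibble(
              channel = ch,
              beat = vapply(segs[drop], function(s) s$beat, integer(1)),
              stage = "copod", reason = "copula_tail_probability",
              score = sc[drop]))
            segs <- segs[-drop]
          }
        }
      }
    }
    chans[[ch]] <- segs
  }
  ids <- purrr::map(chans, ~ vapply(.x, function(s) s$beat, integer(1)))
  common <- Reduce(intersect, ids)
  if (!length(common)) {
    abort("outlier rejection removed all synchronized beats.",
          class = "pk_insufficient_beats")
  }
  for (ch in names(chans)) {
    keep <- vapply(chans[[ch]], function(s) s$beat, integer(1)) %in% common
    drop_ids <- vapply(chans[[ch]][!keep], function(s) s$beat, integer(1))
    if (length(drop_ids)) {
      removed <- bind_rows(removed, tibble(
        channel = ch, beat = drop_ids, stage = "cross_channel",
        reason = "removed_in_other_channel", score = NA_real_))
    }
    chans[[ch]] <- chans[[ch]][keep]
  }
  structure(list(channels = chans, removed = removed), class = "pw_sync")
}

#' Normalize beat durations and ensemble-average each channel
#'
#' Each channel's beats are resampled to the median beat length (in
#' samples) of that channel's ensemble, and the normalized beats are
#' averaged pointwise. The median duration is retained so fiducial times
#' measured on the averaged beat can be reported on the original time
#' scale.
#'
#' @param sync A `pw_sync` (after outlier rejection).
#' @return A `pw_ensemble_avg`: per channel the averaged beat trace, the
#'   median duration in seconds, and the number of beats averaged.
#' @export
normalize_and_average <- function(sync) {
  out <- list()
  for (ch in names(sync$channels)) {
    segs <- sync$channels[[ch]]
    if (!length(segs)) {
      abort(sprintf("channel '%s' has no beats to average.", ch),
            class = "pk_insufficient_beats")
    }
    fs <- segs[[1]]$fs
    lens <- vapply(segs, function(s) length(s$samples), integer(1))
    L <- max(2L, round(stats::median(lens)))
    M <- beat_matrix(segs, L)
    out[[ch]] <- list(
      average = pw_trace(colMeans(M), fs = fs, t0 = 0, kind = ch),
      median_duration = L / fs,
      n_beats = length(segs)
    )
  }
  structure(out, class = "pw_ensemble_avg")
}

#' @export
print.pw_ensemble_avg <- function(x, ...) {
  for (ch in names(x)) {
    cat(sprintf("  %s: %d beats averaged, median duration %.3f s\n",
                ch, x[[ch]]$n_beats, x[[ch]]$median_duration))
  }
  invisible(x)
}
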