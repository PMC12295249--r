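test_that("the onset threshold is 15% of the maximum slope", {
  # smooth trace whose first derivative tops out at exactly 10 u/s
  fs <- 150
  t <- seq(0, 4, by = 1 / fs)
  x <- (10 / (2 * pi)) * sin(2 * pi * t)
  ons <- detect_onsets(pw_trace(x, fs))
  expect_equal(attr(ons, "threshold"), 1.5, tolerance = 0.05)
  expect_length(ons, 4)                      # one upward crossing per cycle
  # constant trace: no onsets
  expect_length(detect_onsets(pw_trace(rep(1, 600), fs)), 0)
})

test_that("noise-free onsets recover the generator truth within one sample", {
  cfg <- sim_config(n_beats = 10,
                    noise_sd = c(ecg = 0, cap = 0, rap = 0, ebi = 0),
                    seed = 17)
  sim <- generate_recording(cfg)
  pp <- preprocess(sim$recording)
  for (ch in c("ebi", "rap", "cap")) {
    ons <- detect_onsets(pp$traces[[ch]])
    truth <- sim$truth$onsets$time_s[sim$truth$onsets$channel == ch]
    expect_length(ons, 10)
    expect_lte(max(abs(ons - truth)) * 150, 1)
  }
})

test_that("period segmentation has the fencepost and duration properties", {
  fs <- 150
  tr <- pw_trace(sin(2 * pi * (0:3000) / fs), fs)
  onsets <- seq(1, 11, by = 1)               # 11 onsets -> 10 beats
  segs <- segment_periods(tr, onsets)
  expect_length(segs, 10)
  expect_equal(vapply(segs, function(s) length(s$samples), integer(1)),
               rep(150L, 10))
  durations <- vapply(segs, function(s) length(s$samples) / s$fs, numeric(1))
  expect_equal(durations, diff(onsets), tolerance = 1 / fs)
  # out-of-bounds beats are dropped and logged
  segs2 <- segment_periods(tr, c(1, 1.2, 4.5, 5.5))
  expect_length(segs2, 1)
  expect_equal(attr(segs2, "removed")$beat, c(1L, 2L))
  expect_error(segment_periods(tr, 1), class = "pk_insufficient_beats")
})

test_that("ECG segments are back-shifted windows with one R wave each", {
  sim <- generate_recording(sim_config(n_beats = 8, seed = 19))
  pp <- preprocess(sim$recording)
  beats <- segment_periods(pp$traces$ebi, detect_onsets(pp$traces$ebi))
  shifted <- select_ecg_segments(pp$traces$ecg, beats, shift = 0.3)
  expect_length(shifted, length(beats))
  for (i in seq_along(beats)) {
    expect_equal(shifted[[i]]$onset_time, beats[[i]]$onset_time - 0.3)
    a <- shifted[[i]]$onset_time
    b <- a + length(shifted[[i]]$samples) / shifted[[i]]$fs
    expect_equal(sum(sim$truth$r_times >= a & sim$truth$r_times < b), 1)
  }
  unshifted <- select_ecg_segments(pp$traces$ecg, beats, shift = 0)
  expect_equal(unshifted[[1]]$onset_time, beats[[1]]$onset_time)
})

dummy_channels <- function(ids_by_channel, offset_by_channel = NULL) {
  chans <- list()
  for (ch in names(ids_by_channel)) {
    off <- if (is.null(offset_by_channel)) 0 else offset_by_channel[[ch]]
    chans[[ch]] <- lapply(ids_by_channel[[ch]], function(k) {
      pulsekit:::new_segment(rep(k, 30), 150, k * 1.0 + off, k * 1.0 + off,
                             as.integer(k), ch)
    })
  }
  chans
}

test_that("synchronization keeps the beat-index intersection", {
  chans <- dummy_channels(list(ebi = 1:10, rap = 2:10, cap = 1:9),
                          list(ebi = 0, rap = 0.02, cap = -0.06))
  sync <- synchronize(chans)
  expect_equal(sync_beat_ids(sync), 2:9)
  for (ch in names(sync$channels)) {
    expect_equal(sort(vapply(sync$channels[[ch]], function(s) s$beat,
                             integer(1))), 2:9)
  }
  all_same <- synchronize(dummy_channels(list(ebi = 1:5, rap = 1:5)))
  expect_equal(sync_beat_ids(all_same), 1:5)
  expect_error(synchronize(dummy_channels(list(ebi = 1:5, rap = integer(0)))),
               class = "pk_insufficient_beats")
})

# an ensemble of repeated template beats with optional per-beat tweaks
toy_sync <- function(n = 10, tweak = NULL, kinds = c("ebi", "rap")) {
  T <- 0.9
  t <- seq(0, T - 1 / 150, by = 1 / 150)
  chans <- list()
  for (ch in kinds) {
    x <- pulsekit:::pulse_shape(ch, t / T)
    chans[[ch]] <- lapply(seq_len(n), function(k) {
      xi <- if (is.null(tweak)) x else tweak(x, k, ch)
      pulsekit:::new_segment(xi, 150, k * T, k * T, as.integer(k), ch)
    })
  }
  structure(list(channels = chans,
                 removed = tibble::tibble(channel = character(),
                                          beat = integer(),
                                          stage = character(),
                                          reason = character(),
                                          score = numeric())),
            class = "pw_sync")
}

test_that("outlier rejection removes exactly the corrupted beat", {
  sync <- toy_sync(11, tweak = function(x, k, ch) if (k == 7) 5 * x else x)
  out <- remove_outliers(sync)
  expect_equal(sync_beat_ids(out), setdiff(1:11, 7))
  expect_true(all(7 %in% out$removed$beat))
  # clean identical ensemble: the degenerate guard keeps everything
  clean <- remove_outliers(toy_sync(10))
  expect_equal(sync_beat_ids(clean), 1:10)
  # a beat of three times the median length fails the length filter
  long <- toy_sync(8, tweak = function(x, k, ch) if (k == 4) rep(x, 3) else x)
  out <- remove_outliers(long)
  expect_false(4 %in% sync_beat_ids(out))
  log4 <- dplyr::filter(out$removed, .data$beat == 4)
  expect_true(all(log4$stage %in% c("length_filter", "cross_channel")))
})

test_that("beat bookkeeping balances and channels stay synchronized", {
  cfg <- sim_config(n_beats = 20, artifact_fraction = 0.1, seed = 23)
  sim <- generate_recording(cfg)
  pp <- preprocess(sim$recording)
  chans <- list()
  for (ch in c("cap", "rap", "ebi")) {
    chans[[ch]] <- segment_periods(pp$traces[[ch]],
                                   detect_onsets(pp$traces[[ch]]))
  }
  chans$ecg <- select_ecg_segments(pp$traces$ecg, chans$ebi)
  sync <- synchronize(chans)
  n_in <- length(sync_beat_ids(sync))
  out <- remove_outliers(sync)
  kept <- sync_beat_ids(out)
  for (ch in names(out$channels)) {
    ids <- sort(vapply(out$channels[[ch]], function(s) s$beat, integer(1)))
    expect_equal(ids, kept)
    n_removed <- length(unique(
      out$removed$beat[out$removed$channel == ch &
                         out$removed$stage != "synchronize"]))
    expect_equal(length(kept) + n_removed, n_in)
  }
  # a clean 15-beat run retains an ensemble in the 5-15 working range
  clean <- generate_recording(sim_config(n_beats = 15, seed = 29))
  pf <- build_patient_features(clean$recording)
  expect_gte(pf$n_beats, 5)
  expect_lte(pf$n_beats, 15)
})

test_that("duration normalization and averaging follow the median", {
  T <- 0.9
  x <- pulsekit:::pulse_shape("ebi", seq(0, 1 - 1e-3, length.out = 150))
  lens <- c(140, 150, 160)
  segs <- lapply(seq_along(lens), function(i) {
    xi <- spline(seq(0, 1, length.out = 150), x,
                 xout = seq(0, 1, length.out = lens[i]))$y
    pulsekit:::new_segment(xi, 150, i * T, i * T, as.integer(i), "ebi")
  })
  sync <- structure(list(channels = list(ebi = segs),
                         removed = tibble::tibble()), class = "pw_sync")
  avg <- normalize_and_average(sync)
  expect_equal(length(avg$ebi$average$samples), 150)
  expect_equal(avg$ebi$median_duration, 1.0)
  # identical beats average to themselves
  same <- toy_sync(6, kinds = "ebi")
  avg <- normalize_and_average(same)
  expect_equal(avg$ebi$average$samples, same$channels$ebi[[1]]$samples,
               tolerance = 1e-9)
})

test_that("averaging n noisy copies shrinks noise like 1/sqrt(n)", {
  withr::with_seed(31, {
    T <- 0.9
    t <- seq(0, T - 1 / 150, by = 1 / 150)
    template <- pulsekit:::pulse_shape("ebi", t / T)
    sigma <- 0.05
    ratios <- vapply(1:20, function(rep) {
      segs <- lapply(1:16, function(k) {
        pulsekit:::new_segment(template + rnorm(length(template), 0, sigma),
                               150, k * T, k * T, as.integer(k), "ebi")
      })
      sync <- structure(list(channels = list(ebi = segs),
                             removed = tibble::tibble()), class = "pw_sync")
      avg <- normalize_and_average(sync)$ebi$average$samples
      sqrt(mean((avg - template)^2)) / (sigma / 4)
    }, numeric(1))
    expect_lt(abs(mean(ratios) - 1), 0.25)
    expect_true(all(ratios > 0.6 & ratios < 1.4))
  })
})
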