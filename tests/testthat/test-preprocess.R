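test_that("smoothing reproduces low-order polynomials and reduces noise", {
  cfg <- preproc_config()
  const <- pw_trace(rep(3.7, 400), fs = 150)
  expect_equal(pw_smooth(const, cfg)$samples, const$samples, tolerance = 1e-9)
  t <- (0:399) / 150
  cubic <- pw_trace(2 - t + 0.5 * t^2 - 0.1 * t^3, fs = 150)
  sm <- pw_smooth(cubic, cfg)
  interior <- 20:380
  expect_equal(sm$samples[interior], cubic$samples[interior],
               tolerance = 1e-9)
  # SNR 10 dB sine: smoothing must strictly reduce the RMSE to the clean sine
  withr::with_seed(1, {
    clean <- sin(2 * pi * 2 * t)
    noise_sd <- sqrt(mean(clean^2) / 10^(10 / 10))
    noisy <- pw_trace(clean + rnorm(length(t), 0, noise_sd), fs = 150)
    sm <- pw_smooth(noisy, cfg)
    expect_lt(sqrt(mean((sm$samples - clean)^2)),
              sqrt(mean((noisy$samples - clean)^2)))
  })
  expect_error(pw_smooth(pw_trace(1:5, fs = 150), cfg),
               class = "pk_invalid_input")
})

test_that("resampling preserves constants, sines and the identity case", {
  const <- pw_trace(rep(2.5, 1000), fs = 1000)
  r <- pw_resample(const, 150)
  expect_equal(r$fs, 150)
  expect_equal(unique(round(r$samples, 12)), 2.5)
  t <- (0:999) / 1000
  sine <- pw_trace(sin(2 * pi * 5 * t), fs = 1000)
  r <- pw_resample(sine, 150)
  tr <- trace_times(r)
  interior <- tr > 0.05 & tr < 0.95
  expect_lt(max(abs(r$samples[interior] - sin(2 * pi * 5 * tr[interior]))),
            1e-3)
  expect_equal(pw_resample(sine, 1000)$samples, sine$samples,
               tolerance = 1e-9)
  # duration preserved within one output sample
  expect_lte(abs((length(r$samples) - 1) / 150 - 0.999), 1 / 150)
})

test_that("polynomial derivatives match analytic values", {
  cfg <- preproc_config()
  t <- (0:599) / 150
  ramp <- pw_trace(2 * t, fs = 150)
  d1 <- pw_derivative(ramp, 1, cfg)
  expect_equal(d1$samples[30:570], rep(2, 541), tolerance = 1e-6)
  omega <- 2 * pi * 1
  sine <- pw_trace(sin(omega * t), fs = 150)
  d3 <- pw_derivative(sine, 3, cfg)
  expected <- -omega^3 * cos(omega * t)
  interior <- 60:540
  expect_lt(max(abs(d3$samples[interior] - expected[interior])) /
              max(abs(expected)), 0.01)
  const <- pw_trace(rep(1, 600), fs = 150)
  for (ord in 1:3) {
    expect_lt(max(abs(pw_derivative(const, ord, cfg)$samples)), 1e-9)
  }
  expect_error(pw_derivative(ramp, 3, preproc_config(sg_polyorder = 2)),
               class = "pk_invalid_parameter")
})

# noise-free pulse train with a known additive drift
drifty_train <- function(drift_per_s = 0, n_beats = 10, fs = 150, T = 0.9,
                         dc = 30) {
  # the DC level emulates the basal offset of raw pressure/impedance traces
  t <- seq(0, n_beats * T, by = 1 / fs)
  x <- pulsekit:::pulse_shape("ebi", (t %% T) / T)
  onsets <- T * (0:(n_beats - 1))
  list(clean = x, trace = pw_trace(x + dc + drift_per_s * t, fs = fs),
       onsets = onsets, t = t)
}

test_that("baseline estimation tracks beat minima and injected drift", {
  for (method in c("minima", "hankel")) {
    cfg <- preproc_config(baseline_method = method)
    flat <- drifty_train(0)
    base <- estimate_baseline(flat$trace, flat$onsets, cfg)
    amp <- diff(range(flat$clean))
    expect_lt(sd(base$samples[20:1300]), 0.02 * amp)
    # 1 unit over 10 s: recovered slope within 10%
    dr <- drifty_train(0.1)
    base <- estimate_baseline(dr$trace, dr$onsets, cfg)
    mid <- dr$t > 1 & dr$t < 8
    slope <- coef(lm(base$samples[mid] ~ dr$t[mid]))[2]
    expect_lt(abs(slope - 0.1), 0.01)
    # baseline passes through each detected minimum
    knots <- pulsekit:::beat_minima(dr$trace, dr$onsets)
    idx <- round((knots$time_s - dr$trace$t0) * dr$trace$fs) + 1
    expect_lt(max(abs(base$samples[idx] - knots$value)), 0.02 * amp)
  }
  expect_error(estimate_baseline(drifty_train(0)$trace, numeric(1)),
               class = "pk_insufficient_beats")
})

test_that("cardiac component extraction is exact subtraction", {
  dr <- drifty_train(0.1)
  cfg <- preproc_config()
  base <- estimate_baseline(dr$trace, dr$onsets, cfg)
  cc <- extract_cardiac_component(dr$trace, base)
  expect_equal(cc$samples + base$samples, dr$trace$samples,
               tolerance = 1e-12)
  # recovered cardiac component matches the drift-free signal
  expect_gt(cor(cc$samples, dr$clean), 0.99)
  # trace equal to its baseline leaves zero
  expect_equal(extract_cardiac_component(base, base)$samples,
               rep(0, length(base$samples)))
  short <- pw_trace(1:10, fs = 150)
  expect_error(extract_cardiac_component(dr$trace, short),
               class = "pk_invalid_input")
})

test_that("preprocessing a clean recording leaves fiducial times in place", {
  cfg0 <- sim_config(n_beats = 8,
                     noise_sd = c(ecg = 0, cap = 0, rap = 0, ebi = 0),
                     drift_amplitude = c(ecg = 0, cap = 0, rap = 0, ebi = 0),
                     seed = 12)
  sim <- generate_recording(cfg0)
  pp <- preprocess(sim$recording)
  ons <- detect_onsets(pp$traces$ebi)
  segs <- segment_periods(pp$traces$ebi, ons)
  with_pp <- detect_fiducials(segs[[3]])
  # same beat cut directly from the raw trace resampled without baseline work
  raw150 <- pw_resample(pw_smooth(sim$recording$traces$ebi), 150)
  segs_raw <- segment_periods(raw150, detect_onsets(raw150))
  no_pp <- detect_fiducials(segs_raw[[3]])
  expect_lte(max(abs(with_pp$time_s - no_pp$time_s)) * 150, 1)
})
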