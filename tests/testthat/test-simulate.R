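test_that("identical configurations give bit-identical recordings", {
  a <- generate_recording(sim_config(n_beats = 6, seed = 7))
  b <- generate_recording(sim_config(n_beats = 6, seed = 7))
  for (ch in names(a$recording$traces)) {
    expect_identical(a$recording$traces[[ch]]$samples,
                     b$recording$traces[[ch]]$samples)
  }
  expect_identical(a$truth$fiducials, b$truth$fiducials)
  expect_identical(a$truth$r_times, b$truth$r_times)
})

test_that("ground truth obeys its construction identities", {
  cfg <- sim_config(n_beats = 8, pat_cap = 0.10, pat_rap = 0.18,
                    pat_ebi = 0.16, path_length = 0.8, seed = 3)
  sim <- generate_recording(cfg)
  tr <- sim$truth
  expect_equal(tr$ptt, 0.18 - 0.10)
  expect_equal(tr$pwv, 10)           # 0.8 / 0.08
  expect_equal(tr$pwv * tr$ptt, tr$path_length)
  # onsets strictly increasing, B = R + configured PAT for every beat
  for (ch in c("cap", "rap", "ebi")) {
    on <- tr$onsets$time_s[tr$onsets$channel == ch]
    expect_true(all(diff(on) > 0))
    expect_equal(on, tr$r_times[seq_along(on)] + tr$pat[[ch]],
                 tolerance = 1e-12)
  }
})

test_that("noise-free EBI onset delay equals the configured arrival time", {
  cfg <- sim_config(n_beats = 6, pat_ebi = 0.16,
                    noise_sd = c(ecg = 0, cap = 0, rap = 0, ebi = 0),
                    seed = 5)
  sim <- generate_recording(cfg)
  delays <- sim$truth$onsets$time_s[sim$truth$onsets$channel == "ebi"] -
    sim$truth$r_times[1:6]
  expect_equal(delays, rep(0.16, 6), tolerance = 1e-12)
})

test_that("artifact injection labels, counts and energies are correct", {
  sim <- generate_recording(sim_config(n_beats = 10, seed = 9))
  # fraction 0 is a no-op
  same <- inject_artifacts(sim$recording, sim$truth, 0)
  expect_identical(same$recording$traces$ebi$samples,
                   sim$recording$traces$ebi$samples)
  expect_length(same$truth$artifact_beats, 0)
  # fraction 0.1 on 10 beats corrupts exactly one
  one <- inject_artifacts(sim$recording, sim$truth, 0.1, seed = 4)
  expect_length(one$truth$artifact_beats, 1)
  # corrupted beats carry at least twice the median clean beat RMS
  big <- inject_artifacts(sim$recording, sim$truth, 0.4, seed = 4)
  tr <- big$recording$traces$rap
  tt <- trace_times(tr)
  beat_rms <- vapply(1:10, function(k) {
    idx <- which(tt >= big$truth$r_times[k] + big$truth$pat[["rap"]] &
                   tt < big$truth$r_times[k + 1] + big$truth$pat[["rap"]])
    x <- tr$samples[idx]
    sqrt(mean((x - median(x))^2))
  }, numeric(1))
  bad <- big$truth$artifact_beats
  expect_true(all(beat_rms[bad] >= 2 * median(beat_rms[-bad])))
  expect_error(inject_artifacts(sim$recording, sim$truth, 0.7),
               class = "pk_invalid_parameter")
})

test_that("cohort generation matches its specification", {
  co <- generate_cohort(cohort_spec(n_beats = 8, seed = 2), signals = FALSE)
  roster <- cohort_roster(co)
  expect_equal(nrow(roster), 44)
  expect_equal(as.integer(table(roster$cad_group)), c(5, 6, 6, 27))
  # same seed reproduces the cohort exactly
  co2 <- generate_cohort(cohort_spec(n_beats = 8, seed = 2), signals = FALSE)
  expect_identical(cohort_roster(co2), roster)
  # degenerate distributions give identical true CPWV everywhere
  dg <- generate_cohort(cohort_spec(pat_ebi_mean = rep(0.14, 4),
                                    pat_ebi_sd = 0, seed = 3),
                        signals = FALSE)
  expect_equal(diff(range(cohort_roster(dg)$true_cpwv)), 0)
  expect_error(cohort_spec(group_sizes = c(5, 6, 6)),
               class = "pk_invalid_parameter")
})

test_that("the configured group contrast is visible in generated cohorts", {
  # group 1 has a longer EBI arrival time, hence lower CPWV, than groups 2-4
  lower <- vapply(1:100, function(s) {
    ro <- cohort_roster(generate_cohort(cohort_spec(seed = s),
                                        signals = FALSE))
    median(ro$true_cpwv[ro$cad_group == 1]) <
      median(ro$true_cpwv[ro$cad_group != 1])
  }, logical(1))
  expect_gte(mean(lower), 0.95)
})
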