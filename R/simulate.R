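#' Configuration for a synthetic four-channel recording
#'
#' Defines the study conditions a simulated catheterization-laboratory
#' recording emulates: a short run of consecutive sinus beats (5-15 is the
#' typical working range), respiratory heart-rate modulation, pressure and
#' impedance pulses delayed from each ECG R peak by channel-specific pulse
#' arrival times, additive measurement noise, slow sinusoidal baseline
#' drift, and (optionally) corrupted beats.
#'
#' @param sampling_rate Native acquisition rate in Hz.
#' @param n_beats Number of complete pulse beats to synthesize (5-15 typical).
#' @param mean_rr Mean RR interval in seconds, in \[0.4, 2.0\].
#' @param resp_rate Respiration rate in Hz modulating the RR series.
#' @param rr_modulation_depth Fractional depth of respiratory RR modulation,
#'   in \[0, 0.3\].
#' @param rr_jitter_sd Additional beat-to-beat RR jitter, as a fraction of
#'   `mean_rr` (default 0.01).
#' @param pat_cap,pat_rap,pat_ebi Pulse arrival times in seconds from the R
#'   peak to the onset of the central pressure, radial pressure and radial
#'   impedance pulses. Must satisfy 0 < pat_cap < pat_rap and pat_ebi > 0.
#' @param path_length Aortic valve to distal radial distance in meters.
#' @param amplitude Named numeric vector of per-channel pulse amplitudes in
#'   channel units.
#' @param offset Named numeric vector of per-channel DC offsets (diastolic
#'   pressure level, basal impedance).
#' @param noise_sd Named numeric vector of per-channel white-noise standard
#'   deviations, in channel units.
#' @param drift_amplitude Named numeric vector of per-channel sinusoidal
#'   baseline drift amplitudes.
#' @param drift_period Drift period in seconds.
#' @param artifact_fraction Fraction of beats to corrupt, in \[0, 0.5\].
#' @param lead_in Quiet padding in seconds before the first R peak (keeps
#'   filter edge effects away from the first beat).
#' @param seed Integer seed; identical configurations give bit-identical
#'   recordings.
#' @return A validated list of class `pw_sim_config`.
#' @export
sim_config <- function(sampling_rate = 500, n_beats = 12, mean_rr = 0.85,
                       resp_rate = 0.25, rr_modulation_depth = 0.05,
                       rr_jitter_sd = 0.01,
                       pat_cap = 0.09, pat_rap = 0.17, pat_ebi = 0.15,
                       path_length = 0.8,
                       amplitude = c(ecg = 1, cap = 40, rap = 45, ebi = 1),
                       offset = c(ecg = 0, cap = 80, rap = 75, ebi = 100),
                       noise_sd = c(ecg = 0.01, cap = 0.4, rap = 0.45,
                                    ebi = 0.01),
                       drift_amplitude = c(ecg = 0.02, cap = 2, rap = 2,
                                           ebi = 0.08),
                       drift_period = 10, artifact_fraction = 0,
                       lead_in = 1, seed = 1L) {
  if (sampling_rate <= 0) {
    abort("`sampling_rate` must be positive.", class = "pk_invalid_parameter")
  }
  if (mean_rr < 0.4 || mean_rr > 2.0) {
    abort("`mean_rr` must lie in [0.4, 2.0] s.",
          class = "pk_invalid_parameter")
  }
  if (rr_modulation_depth < 0 || rr_modulation_depth > 0.3) {
    abort("`rr_modulation_depth` must lie in [0, 0.3].",
          class = "pk_invalid_parameter")
  }
  if (!(pat_cap > 0 && pat_cap < pat_rap)) {
    abort("need 0 < pat_cap < pat_rap (central pulse leads peripheral).",
          class = "pk_invalid_parameter")
  }
  if (pat_ebi <= 0) {
    abort("`pat_ebi` must be positive.", class = "pk_invalid_parameter")
  }
  if (artifact_fraction < 0 || artifact_fraction > 0.5) {
    abort("`artifact_fraction` must lie in [0, 0.5].",
          class = "pk_invalid_parameter")
  }
  if (n_beats < 2) {
    abort("`n_beats` must be at least 2.", class = "pk_invalid_parameter")
  }
  for (nm in c("amplitude", "offset", "noise_sd", "drift_amplitude")) {
    v <- get(nm)
    if (!all(ALL_KINDS %in% names(v))) {
      abort(sprintf("`%s` must name all channels: %s.", nm,
                    paste(ALL_KINDS, collapse = ", ")),
            class = "pk_invalid_parameter")
    }
  }
  structure(
    list(sampling_rate = sampling_rate, n_beats = as.integer(n_beats),
         mean_rr = mean_rr, resp_rate = resp_rate,
         rr_modulation_depth = rr_modulation_depth,
         rr_jitter_sd = rr_jitter_sd,
         pat_cap = pat_cap, pat_rap = pat_rap, pat_ebi = pat_ebi,
         path_length = path_length, amplitude = amplitude, offset = offset,
         noise_sd = noise_sd, drift_amplitude = drift_amplitude,
         drift_period = drift_period, artifact_fraction = artifact_fraction,
         lead_in = lead_in, seed = as.integer(seed)),
    class = "pw_sim_config"
  )
}

# narrow R-wave: cos^2 spike of total width ~20 ms
ecg_spike <- function(t, r_time, width = 0.02) {
  s <- (t - r_time) / (width / 2)
  v <- numeric(length(t))
  inside <- abs(s) < 1
  v[inside] <- cos(pi * s[inside] / 2)^2
  v
}

#' Generate a synthetic four-channel recording with ground truth
#'
#' Produces simultaneous ECG, central aortic pressure, radial pressure and
#' radial bioimpedance traces on one uniform grid. Every pulse channel is a
#' concatenation of beat templates whose onsets lag the corresponding ECG R
#' peak by the configured pulse arrival time; RR intervals follow
#' `mean_rr * (1 + depth * sin(2 pi resp_rate t))` plus a small jitter.
#' The returned ground truth carries the R times, per-channel onset (B)
#' times, dense-grid fiducial times for every beat, the configured arrival
#' times, and the implied transit time and pulse wave velocity.
#'
#' @param config A [sim_config()].
#' @return A list of class `pw_sim` with elements `recording`
#'   (a [pw_recording()]) and `truth` (class `pw_ground_truth`).
#' @examples
#' sim <- generate_recording(sim_config(n_beats = 6, seed = 2))
#' sim$truth$pwv
#' @export
generate_recording <- function(config = sim_config()) {
  if (!inherits(config, "pw_sim_config")) {
    abort("`config` must be a pw_sim_config.", class = "pk_invalid_parameter")
  }
  withr::with_seed(config$seed, {
    nb <- config$n_beats
    # RR series: respiratory modulation evaluated at each beat's start time,
    # plus zero-mean jitter
    r_times <- numeric(nb + 1)
    rr <- numeric(nb)
    r_times[1] <- config$lead_in
    for (k in seq_len(nb)) {
      rr[k] <- config$mean_rr *
        (1 + config$rr_modulation_depth *
           sin(2 * pi * config$resp_rate * r_times[k])) +
        rnorm(1, 0, config$rr_jitter_sd * config$mean_rr)
      rr[k] <- max(rr[k], 0.4)
      r_times[k + 1] <- r_times[k] + rr[k]
    }
    total <- r_times[nb + 1] + max(config$pat_cap, config$pat_rap,
                                   config$pat_ebi) + config$lead_in
    fs <- config$sampling_rate
    t <- seq(0, total, by = 1 / fs)

    drift_phase <- runif(4, 0, 2 * pi)
    names(drift_phase) <- ALL_KINDS

    traces <- list()
    ecg <- numeric(length(t))
    for (k in seq_len(nb + 1)) ecg <- ecg + ecg_spike(t, r_times[k])
    ecg <- config$amplitude[["ecg"]] * ecg + config$offset[["ecg"]] +
      config$drift_amplitude[["ecg"]] *
        sin(2 * pi * t / config$drift_period + drift_phase[["ecg"]]) +
      rnorm(length(t), 0, config$noise_sd[["ecg"]])
    traces$ecg <- pw_trace(ecg, fs, t0 = 0, kind = "ecg", units = "mV")

    pats <- c(cap = config$pat_cap, rap = config$pat_rap,
              ebi = config$pat_ebi)
    onset_times <- list()
    fiducials <- list()
    for (ch in PULSE_KINDS) {
      x <- numeric(length(t))
      onsets <- r_times[seq_len(nb)] + pats[[ch]]
      for (k in seq_len(nb)) {
        i0 <- which(t >= onsets[k] & t < onsets[k] + rr[k])
        x[i0] <- x[i0] + pulse_shape(ch, (t[i0] - onsets[k]) / rr[k])
      }
      x <- config$amplitude[[ch]] * x + config$offset[[ch]] +
        config$drift_amplitude[[ch]] *
          sin(2 * pi * t / config$drift_period + drift_phase[[ch]]) +
        rnorm(length(t), 0, config$noise_sd[[ch]])
      units <- if (ch == "ebi") "a.u." else "mmHg"
      traces[[ch]] <- pw_trace(x, fs, t0 = 0, kind = ch, units = units)
      onset_times[[ch]] <- onsets

      # dense-grid oracle fiducials, beat-local then absolute
      fiducials[[ch]] <- purrr::map_dfr(seq_len(nb), function(k) {
        tpl <- generate_pulse_template(ch, min(max(rr[k], 0.4), 2.0))
        mutate(tpl$fiducials, beat = k, channel = ch,
               time_abs_s = .data$time_s + onsets[k])
      })
    }

    truth <- structure(
      list(
        r_times = r_times,
        rr = rr,
        onsets = purrr::map_dfr(PULSE_KINDS, function(ch) {
          tibble(channel = ch, beat = seq_len(nb),
                 time_s = onset_times[[ch]])
        }),
        fiducials = bind_rows(fiducials) |>
          select("channel", "beat", "point", "time_s", "time_abs_s",
                 "amplitude", "detected"),
        pat = pats,
        ptt = config$pat_rap - config$pat_cap,
        pwv = config$path_length / (config$pat_rap - config$pat_cap),
        path_length = config$path_length,
        artifact_beats = integer(0),
        config = config
      ),
      class = "pw_ground_truth"
    )

    sim <- structure(
      list(recording = pw_recording(traces, patient_id = "sim"),
           truth = truth),
      class = "pw_sim"
    )
    if (config$artifact_fraction > 0) {
      sim <- inject_artifacts(sim$recording, sim$truth,
                              config$artifact_fraction,
                              seed = config$seed + 1L)
    }
    sim
  })
}

#' @export
print.pw_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<pw_ground_truth> %d beats; PAT cap/rap/ebi = %.3f/%.3f/%.3f s; PTT = %.3f s; PWV = %.2f m/s; %d artifact beat(s)\n",
    length(x$rr), x$pat[["cap"]], x$pat[["rap"]], x$pat[["ebi"]],
    x$ptt, x$pwv, length(x$artifact_beats)))
  invisible(x)
}

#' Corrupt a fraction of beats in a recording
#'
#' Emulates electrode movement and measurement disturbances by corrupting
#' `round(artifact_fraction * n_beats)` randomly chosen beats across all
#' channels. Two corruption modes are cycled deterministically: amplitude
#' scaling (x4 about the beat minimum) and a cosine-tapered mid-beat step
#' offset of twice the channel pulse amplitude. Both modes leave the signal
#' continuous at the beat boundaries and preserve the per-beat minimum, so
#' a corrupted beat distorts neither its neighbours nor the baseline
#' estimate -- the corruption stays confined to the labelled beat.
#' Corrupted beat indices are recorded in the ground truth.
#'
#' @param recording A [pw_recording()].
#' @param truth The matching `pw_ground_truth`.
#' @param artifact_fraction Fraction of beats to corrupt, in \[0, 0.5\].
#' @param seed Integer seed for beat selection.
#' @return A `pw_sim` list with the corrupted recording and updated truth.
#' @export
inject_artifacts <- function(recording, truth, artifact_fraction,
                             seed = 1L) {
  if (artifact_fraction < 0 || artifact_fraction > 0.5) {
    abort("`artifact_fraction` must lie in [0, 0.5].",
          class = "pk_invalid_parameter")
  }
  nb <- length(truth$rr)
  n_bad <- round(artifact_fraction * nb)
  if (n_bad == 0) {
    return(structure(list(recording = recording, truth = truth),
                     class = "pw_sim"))
  }
  cfg <- truth$config
  withr::with_seed(as.integer(seed), {
    bad <- sort(sample(nb, n_bad))
    modes <- rep(c("scale", "step"), length.out = n_bad)
    traces <- recording$traces
    for (b in seq_along(bad)) {
      k <- bad[b]
      for (ch in names(traces)) {
        tr <- traces[[ch]]
        pat <- if (ch == "ecg") 0 else truth$pat[[ch]]
        a <- truth$r_times[k] + pat
        bnd <- truth$r_times[k + 1] + pat
        tt <- trace_times(tr)
        idx <- which(tt >= a & tt < bnd)
        if (length(idx) < 8) next
        amp <- cfg$amplitude[[ch]]
        x <- tr$samples
        if (modes[b] == "scale") {
          base <- min(x[idx])
          x[idx] <- base + 4 * (x[idx] - base)
        } else {
          # +2*amp plateau over the middle half, 60 ms cosine tapers;
          # stays clear of the onset regions used for baseline minima
          u <- (tt[idx] - a) / (bnd - a)
          taper <- 0.06 / (bnd - a)
          ramp <- pmin(pmax((u - 0.25) / taper, 0),
                       pmax((0.75 - u) / taper, 0), 1)
          x[idx] <- x[idx] + 2 * amp * ramp
        }
        tr$samples <- x
        traces[[ch]] <- tr
      }
    }
    truth$artifact_beats <- sort(union(truth$artifact_beats, bad))
    structure(
      list(recording = pw_recording(traces, recording$patient_id),
           truth = truth),
      class = "pw_sim"
    )
  })
}

#' Specification of a synthetic patient cohort
#'
#' Group structure mirrors a coronary-disease staging into four groups
#' (1 = normal coronaries through 4 = significant disease), with a
#' per-group distribution of the EBI pulse arrival time so that disease
#' stages can differ in their complementary pulse wave velocity.
#'
#' @param group_sizes Integer vector of length 4: patients per CAD group.
#' @param pat_ebi_mean Numeric length 4: per-group mean EBI pulse arrival
#'   time in seconds.
#' @param pat_ebi_sd Numeric length 4 (or 1, recycled): per-group SD in
#'   seconds, all >= 0.
#' @param risk_prevalence Named numeric vector of risk-factor prevalences
#'   (fractions) for the six tracked factors.
#' @param path_length_mean,path_length_sd Distribution of the measured
#'   aortic-valve-to-radial path length in meters.
#' @param mean_rr_range Range the per-patient mean RR interval is drawn from.
#' @param n_beats Beats per recording.
#' @param seed Integer seed.
#' @return A validated list of class `pw_cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(5, 6, 6, 27),
                        pat_ebi_mean = c(0.151, 0.129, 0.129, 0.129),
                        pat_ebi_sd = 0.010,
                        risk_prevalence = c(hypertension = 0.932,
                                            dyslipidemia_untreated = 0.182,
                                            bmi_over_35 = 0.091,
                                            smoking = 0.614,
                                            diabetes = 0.182,
                                            vascular_pathology = 0.091),
                        path_length_mean = 0.8, path_length_sd = 0.05,
                        mean_rr_range = c(0.78, 0.92),
                        n_beats = 12, seed = 1L) {
  if (length(group_sizes) != 4 || any(group_sizes < 0)) {
    abort("`group_sizes` must be four non-negative counts.",
          class = "pk_invalid_parameter")
  }
  pat_ebi_sd <- rep_len(pat_ebi_sd, 4)
  if (any(pat_ebi_sd < 0) || path_length_sd < 0) {
    abort("standard deviations must be >= 0.",
          class = "pk_invalid_parameter")
  }
  structure(
    list(group_sizes = as.integer(group_sizes),
         n_patients = as.integer(sum(group_sizes)),
         pat_ebi_mean = pat_ebi_mean, pat_ebi_sd = pat_ebi_sd,
         risk_prevalence = risk_prevalence,
         path_length_mean = path_length_mean,
         path_length_sd = path_length_sd,
         mean_rr_range = mean_rr_range,
         n_beats = as.integer(n_beats), seed = as.integer(seed)),
    class = "pw_cohort_spec"
  )
}

#' Generate a synthetic cohort of recordings with patient metadata
#'
#' Draws per-patient arrival times from the group distributions, builds a
#' patient record (CAD stage consistent stenosis and flags, risk factors,
#' path length) and, unless `signals = FALSE`, synthesizes the four-channel
#' recording for each patient.
#'
#' @param spec A [cohort_spec()].
#' @param signals If `FALSE`, skip waveform synthesis and return only truth
#'   and patient records (fast; useful for cohort-level statistics of the
#'   generator itself).
#' @return A list of class `pw_cohort`: per patient a list with `recording`
#'   (or `NULL`), `truth`, and `record` (a [patient_record()] row). The
#'   combined roster is available via [cohort_roster()].
#' @export
generate_cohort <- function(spec = cohort_spec(), signals = TRUE) {
  if (!inherits(spec, "pw_cohort_spec")) {
    abort("`spec` must be a pw_cohort_spec.", class = "pk_invalid_parameter")
  }
  withr::with_seed(spec$seed, {
    groups <- rep(1:4, times = spec$group_sizes)
    n <- spec$n_patients
    pat_ebi <- pmax(rnorm(n, spec$pat_ebi_mean[groups],
                          spec$pat_ebi_sd[groups]), 0.06)
    pat_cap <- pmax(rnorm(n, 0.090, 0.005), 0.05)
    # radial pressure arrives a little after the impedance pulse onset
    pat_rap <- pat_ebi + pmax(rnorm(n, 0.020, 0.004), 0.008)
    path_len <- pmin(pmax(rnorm(n, spec$path_length_mean,
                                spec$path_length_sd), 0.6), 1.1)
    mean_rr <- runif(n, spec$mean_rr_range[1], spec$mean_rr_range[2])
    age <- round(runif(n, 45, 74))
    sex <- sample(c("m", "f"), n, replace = TRUE, prob = c(0.727, 0.273))
    flags <- purrr::map(spec$risk_prevalence,
                        ~ runif(n) < .x)
    sten <- numeric(n); revasc <- logical(n); three_v <- logical(n)
    for (i in seq_len(n)) {
      sten[i] <- switch(groups[i],
                        0,
                        runif(1, 10, 50),
                        runif(1, 51, 75),
                        runif(1, 51, 100))
      if (groups[i] == 4) {
        revasc[i] <- TRUE
        three_v[i] <- runif(1) < 0.3
      }
    }
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      rec_row <- patient_record(
        patient_id = sprintf("P%03d", i), age = age[i], sex = sex[i],
        path_length = path_len[i],
        hypertension = flags$hypertension[i],
        dyslipidemia_untreated = flags$dyslipidemia_untreated[i],
        bmi_over_35 = flags$bmi_over_35[i],
        smoking = flags$smoking[i],
        diabetes = flags$diabetes[i],
        vascular_pathology = flags$vascular_pathology[i],
        stenosis_max = sten[i],
        revascularization_object = revasc[i],
        three_vessel = three_v[i]
      )
      rec_row$cad_group <- groups[i]
      cfg <- sim_config(
        n_beats = spec$n_beats, mean_rr = mean_rr[i],
        pat_cap = pat_cap[i], pat_rap = pat_rap[i], pat_ebi = pat_ebi[i],
        path_length = path_len[i],
        seed = spec$seed + 1000L + i
      )
      if (signals) {
        sim <- generate_recording(cfg)
        sim$recording$patient_id <- rec_row$patient_id
        patients[[i]] <- list(recording = sim$recording, truth = sim$truth,
                              record = rec_row)
      } else {
        truth <- structure(
          list(pat = c(cap = pat_cap[i], rap = pat_rap[i],
                       ebi = pat_ebi[i]),
               ptt = pat_rap[i] - pat_cap[i],
               pwv = path_len[i] / (pat_rap[i] - pat_cap[i]),
               path_length = path_len[i], config = cfg),
          class = "pw_ground_truth"
        )
        patients[[i]] <- list(recording = NULL, truth = truth,
                              record = rec_row)
      }
    }
    structure(list(patients = patients, spec = spec), class = "pw_cohort")
  })
}

#' Combined patient roster of a synthetic cohort
#'
#' @param cohort A `pw_cohort` from [generate_cohort()].
#' @return Tibble with one row per patient: the patient record plus the
#'   generator's true arrival times, transit time and velocities.
#' @export
cohort_roster <- function(cohort) {
  if (!inherits(cohort, "pw_cohort")) {
    abort("`cohort` must be a pw_cohort.", class = "pk_invalid_parameter")
  }
  purrr::map_dfr(cohort$patients, function(p) {
    mutate(p$record,
           true_pat_ebi = p$truth$pat[["ebi"]],
           true_pat_rap = p$truth$pat[["rap"]],
           true_pat_cap = p$truth$pat[["cap"]],
           true_ptt = p$truth$ptt,
           true_pwv = p$truth$pwv,
           true_cpwv = 0.8 / p$truth$pat[["ebi"]])
  })
}

#' @export
print.pw_cohort <- function(x, ...) {
  cat(sprintf("<pw_cohort> %d patients (groups %s)\n",
              x$spec$n_patients,
              paste(x$spec$group_sizes, collapse = "/")))
  invisible(x)
}
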