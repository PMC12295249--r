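#' Per-beat R-to-onset delays and their medians
#'
#' For every synchronized beat the delay from the ECG R peak to the pulse
#' onset (B point) of each pulse channel is the per-beat pulse arrival
#' time. The final per-channel arrival time is the median delay across
#' beats; beats where the onset precedes the R peak are physiologically
#' invalid, flagged, and excluded from the median.
#'
#' @param sync A `pw_sync` containing an `ecg` channel plus pulse channels.
#' @param polarity R-peak polarity passed to [detect_r_peak()].
#' @return A list with `beats` (tibble: beat, r_time, per-channel onset and
#'   delay columns) and `medians` (named numeric vector of per-channel
#'   median delays in seconds).
#' @export
compute_rb_delays <- function(sync, polarity = "auto") {
  if (!"ecg" %in% names(sync$channels)) {
    abort("ensemble has no ECG channel.", class = "pk_missing_channel")
  }
  ecg_segs <- sync$channels$ecg
  r_times <- tibble(
    beat = vapply(ecg_segs, function(s) s$beat, integer(1)),
    r_time = vapply(ecg_segs, detect_r_peak, numeric(1),
                    polarity = polarity)
  )
  pulse <- setdiff(names(sync$channels), "ecg")
  beats <- r_times
  for (ch in pulse) {
    ons <- tibble(
      beat = vapply(sync$channels[[ch]], function(s) s$beat, integer(1)),
      onset = vapply(sync$channels[[ch]], function(s) s$onset_time,
                     numeric(1))
    )
    names(ons)[2] <- paste0("onset_", ch)
    beats <- left_join(beats, ons, by = "beat")
    delay <- beats[[paste0("onset_", ch)]] - beats$r_time
    invalid <- !is.na(delay) & delay <= 0
    delay[invalid] <- NA_real_
    beats[[paste0("rb_delay_", ch)]] <- delay
    if (any(invalid)) {
      warn(sprintf("%d beat(s) on channel '%s' had onset before the R peak; excluded.",
                   sum(invalid), ch))
    }
  }
  medians <- vapply(pulse, function(ch) {
    stats::median(beats[[paste0("rb_delay_", ch)]], na.rm = TRUE)
  }, numeric(1))
  list(beats = beats, medians = medians)
}

#' Pulse transit time between the central and radial sites
#'
#' `PTT = PAT_RAP - PAT_CAP`: the central pulse must lead the peripheral
#' one, so a non-positive difference is a physiology error, not a value.
#'
#' @param pat_rap,pat_cap Arrival times in seconds.
#' @return Transit time in seconds.
#' @export
compute_ptt <- function(pat_rap, pat_cap) {
  ptt <- pat_rap - pat_cap
  if (any(!is.na(ptt) & ptt <= 0)) {
    abort("PAT_RAP must exceed PAT_CAP (central pulse leads peripheral).",
          class = "pk_invalid_physiology")
  }
  ptt
}

#' Pulse wave velocity over the measured arterial path
#'
#' `PWV = L / (PAT_RAP - PAT_CAP)` with `L` the measured aortic-valve to
#' distal-radial distance in meters.
#'
#' @param path_length Path length in meters (> 0).
#' @param pat_rap,pat_cap Arrival times in seconds.
#' @return Velocity in m/s.
#' @export
compute_pwv <- function(path_length, pat_rap, pat_cap) {
  if (any(!is.na(path_length) & path_length <= 0)) {
    abort("`path_length` must be positive.", class = "pk_invalid_parameter")
  }
  path_length / compute_ptt(pat_rap, pat_cap)
}

#' Complementary pulse wave velocity from the EBI arrival time
#'
#' `CPWV = 0.8 / PAT_EBI`: a cuffless velocity surrogate dividing a fixed
#' representative aorta-to-radial length (0.8 m, the cohort median) by the
#' ECG-R-to-impedance-onset arrival time. Unlike PWV it contains the
#' pre-ejection period, so its absolute values run lower than PWV and the
#' two are not interchangeable.
#'
#' @param pat_ebi EBI pulse arrival time in seconds (> 0).
#' @param fixed_length Fixed path length in meters (default 0.8).
#' @return Velocity in m/s.
#' @export
compute_cpwv <- function(pat_ebi, fixed_length = 0.8) {
  if (any(!is.na(pat_ebi) & pat_ebi <= 0)) {
    abort("`pat_ebi` must be positive.", class = "pk_invalid_input")
  }
  fixed_length / pat_ebi
}

#' Pipeline configuration bundle
#'
#' @param preproc A [preproc_config()].
#' @param fiducial A [fiducial_config()].
#' @param outlier An [outlier_config()].
#' @param ecg_shift Back-shift for ECG segment selection in seconds.
#' @param cpwv_length Fixed path length for CPWV in meters.
#' @return A list of class `pw_pipeline_config`.
#' @export
pipeline_config <- function(preproc = preproc_config(),
                            fiducial = fiducial_config(preproc = preproc),
                            outlier = outlier_config(),
                            ecg_shift = 0.3, cpwv_length = 0.8) {
  structure(list(preproc = preproc, fiducial = fiducial, outlier = outlier,
                 ecg_shift = ecg_shift, cpwv_length = cpwv_length),
            class = "pw_pipeline_config")
}

#' Run the full per-patient pipeline on a recording
#'
#' Chains every stage: preprocessing (smooth, resample, baseline removal),
#' onset detection on the cardiac component, period segmentation, ECG
#' segment selection, cross-channel synchronization, three-step outlier
#' rejection, R-peak and onset timing, and duration-normalized ensemble
#' averaging with fiducial detection on the averaged beats. Returns one
#' tidy feature row per patient.
#'
#' @param recording A [pw_recording()] with an `ecg` channel and at least
#'   one pulse channel. PWV requires `cap` and `rap`; CPWV requires `ebi`.
#' @param patient A [patient_record()] row (supplies the measured path
#'   length) or `NULL` (PWV then uses 0.8 m).
#' @param config A [pipeline_config()].
#' @return A one-row tibble of class `pw_patient_features` with columns
#'   `patient_id`, `n_beats`, per-channel `rb_delay_*_s`, `pat_*_s`,
#'   `ptt_s`, `pwv_mps`, `cpwv_mps`. Ensemble-averaged fiducial times (on
#'   the original time scale) are attached as attribute `"fiducial_times"`,
#'   and per-stage beat bookkeeping as attribute `"log"`.
#' @export
build_patient_features <- function(recording, patient = NULL,
                                   config = pipeline_config()) {
  if (!inherits(recording, "pw_recording")) {
    abort("`recording` must be a pw_recording.", class = "pk_invalid_input")
  }
  if (!"ecg" %in% names(recording$traces)) {
    abort("recording has no ECG channel.", class = "pk_missing_channel")
  }
  pulse <- intersect(PULSE_KINDS, names(recording$traces))
  if (!length(pulse)) {
    abort("recording has no pulse channel.", class = "pk_missing_channel")
  }

  pp <- preprocess(recording, config$preproc)
  stage_log <- list()

  channels <- list()
  for (ch in pulse) {
    ons <- detect_onsets(pp$traces[[ch]], config$preproc)
    if (length(ons) < 2) {
      abort(sprintf("stage onset-detection: fewer than 2 onsets on '%s'.", ch),
            class = "pk_insufficient_beats")
    }
    channels[[ch]] <- segment_periods(pp$traces[[ch]], ons)
    stage_log[[paste0("onsets_", ch)]] <- length(ons)
  }
  ref <- if ("ebi" %in% pulse) "ebi" else pulse[1]
  channels$ecg <- select_ecg_segments(pp$traces$ecg, channels[[ref]],
                                      shift = config$ecg_shift)
  sync <- synchronize(channels, reference = ref)
  stage_log$synchronized <- length(sync_beat_ids(sync))
  sync <- remove_outliers(sync, config$outlier)
  kept <- sync_beat_ids(sync)
  stage_log$kept <- length(kept)

  delays <- compute_rb_delays(sync)
  med <- delays$medians
  pat_cap <- if ("cap" %in% names(med)) med[["cap"]] else NA_real_
  pat_rap <- if ("rap" %in% names(med)) med[["rap"]] else NA_real_
  pat_ebi <- if ("ebi" %in% names(med)) med[["ebi"]] else NA_real_

  path_len <- if (!is.null(patient)) patient$path_length[1] else 0.8
  ptt <- if (!is.na(pat_rap) && !is.na(pat_cap)) {
    compute_ptt(pat_rap, pat_cap)
  } else NA_real_
  pwv <- if (!is.na(ptt)) path_len / ptt else NA_real_
  cpwv <- if (!is.na(pat_ebi)) {
    compute_cpwv(pat_ebi, config$cpwv_length)
  } else NA_real_

  avg <- normalize_and_average(sync)
  fid_times <- purrr::map_dfr(setdiff(names(avg), "ecg"), function(ch) {
    seg <- new_segment(avg[[ch]]$average$samples, avg[[ch]]$average$fs,
                       0, 0, 0L, ch)
    detect_fiducials(seg, config$fiducial) |>
      select("channel", "point", "time_s", "amplitude", "detected")
  })

  out <- tibble(
    patient_id = if (!is.null(patient)) patient$patient_id[1]
                 else recording$patient_id,
    n_beats = length(kept),
    rb_delay_ebi_s = pat_ebi, rb_delay_rap_s = pat_rap,
    rb_delay_cap_s = pat_cap,
    pat_ebi_s = pat_ebi, pat_rap_s = pat_rap, pat_cap_s = pat_cap,
    ptt_s = ptt, pwv_mps = pwv, cpwv_mps = cpwv
  )
  attr(out, "fiducial_times") <- fid_times
  attr(out, "log") <- stage_log
  attr(out, "removed") <- sync$removed
  class(out) <- c("pw_patient_features", class(out))
  out
}
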