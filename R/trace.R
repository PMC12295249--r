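#' Construct a uniformly sampled single-channel trace
#'
#' A trace is the elementary signal container of the package: a numeric
#' vector sampled on a uniform grid, together with its sampling rate, the
#' absolute time of its first sample, and the channel kind. Channel units
#' (mV for ECG, mmHg for pressures, arbitrary impedance units for EBI) are
#' carried as metadata only; every detector in the package is invariant to
#' amplitude scale and offset, so units never enter a computation.
#'
#' @param samples Numeric vector of signal values (finite, length >= 2).
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Absolute time of the first sample, in seconds.
#' @param kind Channel kind: one of `"ecg"`, `"cap"`, `"rap"`, `"ebi"`, or a
#'   free-form label for generic signals.
#' @param units Unit label carried as metadata.
#'
#' @return An object of class `pw_trace`.
#' @examples
#' tr <- pw_trace(sin(2 * pi * seq(0, 1, by = 0.01)), fs = 100)
#' tr
#' @export
pw_trace <- function(samples, fs, t0 = 0, kind = "generic", units = "") {
  if (!is.numeric(samples) || length(samples) < 2) {
    abort("`samples` must be a numeric vector of length >= 2.",
          class = "pk_invalid_input")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite.", class = "pk_invalid_input")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).",
          class = "pk_invalid_parameter")
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         t0 = as.numeric(t0), kind = kind, units = units),
    class = "pw_trace"
  )
}

#' @export
print.pw_trace <- function(x, ...) {
  cat(sprintf("<pw_trace> %s: %d samples @ %g Hz, t0 = %.4g s (%.3g s)\n",
              x$kind, length(x$samples), x$fs, x$t0,
              (length(x$samples) - 1) / x$fs))
  invisible(x)
}

#' @export
length.pw_trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param trace A [pw_trace()].
#' @return Numeric vector of absolute times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

#' @export
as_tibble.pw_trace <- function(x, ...) {
  tibble(time_s = trace_times(x), value = x$samples, kind = x$kind)
}

#' Construct a multi-channel recording
#'
#' Bundles per-channel traces covering a common time interval. An ECG channel
#' must be present whenever timing features relative to the R peak are to be
#' computed downstream.
#'
#' @param traces Named list of [pw_trace()] objects; names are channel kinds.
#' @param patient_id Identifier carried through the pipeline.
#' @return An object of class `pw_recording`.
#' @export
pw_recording <- function(traces, patient_id = "unknown") {
  if (!is.list(traces) || is.null(names(traces)) || any(names(traces) == "")) {
    abort("`traces` must be a named list of pw_trace objects.",
          class = "pk_invalid_input")
  }
  for (nm in names(traces)) {
    if (!inherits(traces[[nm]], "pw_trace")) {
      abort(sprintf("channel '%s' is not a pw_trace.", nm),
            class = "pk_invalid_input")
    }
  }
  spans <- map(traces, function(tr) range(trace_times(tr)))
  lo <- max(map_dbl(spans, 1)); hi <- min(map_dbl(spans, 2))
  if (hi - lo < 2) {
    abort("channels must share a common time interval of at least 2 s.",
          class = "pk_invalid_input")
  }
  structure(list(traces = traces, patient_id = patient_id),
            class = "pw_recording")
}

#' @export
print.pw_recording <- function(x, ...) {
  cat(sprintf("<pw_recording> patient %s, %d channel(s): %s\n",
              x$patient_id, length(x$traces),
              paste(names(x$traces), collapse = ", ")))
  for (tr in x$traces) print(tr)
  invisible(x)
}

#' Tidy a recording into a wide tibble
#'
#' Channels must share one uniform sampling grid (as produced by
#' [generate_recording()] and [read_recording()]).
#'
#' @param x A `pw_recording`.
#' @param ... Unused.
#' @return A tibble with a `time_s` column and one column per channel.
#' @export
as_tibble.pw_recording <- function(x, ...) {
  fs <- map_dbl(x$traces, "fs"); t0 <- map_dbl(x$traces, "t0")
  ns <- map_dbl(x$traces, ~ length(.x$samples))
  if (length(unique(fs)) != 1 || max(abs(t0 - t0[1])) > 1e-9 / fs[1] ||
      length(unique(ns)) != 1) {
    abort("channels are not on a shared sampling grid; tidy them per channel.",
          class = "pk_invalid_input")
  }
  out <- tibble(time_s = trace_times(x$traces[[1]]))
  for (nm in names(x$traces)) out[[nm]] <- x$traces[[nm]]$samples
  out
}

#' Describe a patient for cohort analyses
#'
#' One row per patient: identifiers, the measured aortic-valve-to-radial
#' path length used in pulse wave velocity, the six cardiovascular risk-factor
#' flags, and the coronary angiography findings that drive disease staging.
#'
#' @param patient_id Identifier.
#' @param age Age in years.
#' @param sex `"m"` or `"f"`.
#' @param path_length Aortic valve to distal radial artery distance in meters
#'   (must lie in \[0.4, 1.2\]).
#' @param hypertension,dyslipidemia_untreated,bmi_over_35,smoking,diabetes,vascular_pathology
#'   Logical risk-factor flags.
#' @param stenosis_max Maximal coronary diameter stenosis in percent (0-100).
#' @param revascularization_object Whether any lesion is a revascularization
#'   target.
#' @param three_vessel Whether three-vessel disease is present.
#' @return A one-row tibble of class `pw_patient_record`.
#' @export
patient_record <- function(patient_id, age = NA_real_, sex = NA_character_,
                           path_length = 0.8,
                           hypertension = FALSE, dyslipidemia_untreated = FALSE,
                           bmi_over_35 = FALSE, smoking = FALSE,
                           diabetes = FALSE, vascular_pathology = FALSE,
                           stenosis_max = 0, revascularization_object = FALSE,
                           three_vessel = FALSE) {
  if (!is.na(stenosis_max) && (stenosis_max < 0 || stenosis_max > 100)) {
    abort("`stenosis_max` must lie in [0, 100] percent.",
          class = "pk_invalid_parameter")
  }
  if (!is.na(path_length) && (path_length < 0.4 || path_length > 1.2)) {
    abort("`path_length` must lie in [0.4, 1.2] m.",
          class = "pk_invalid_parameter")
  }
  out <- tibble(
    patient_id = as.character(patient_id), age = age, sex = sex,
    path_length = path_length,
    hypertension = hypertension,
    dyslipidemia_untreated = dyslipidemia_untreated,
    bmi_over_35 = bmi_over_35, smoking = smoking, diabetes = diabetes,
    vascular_pathology = vascular_pathology,
    stenosis_max = stenosis_max,
    revascularization_object = revascularization_object,
    three_vessel = three_vessel
  )
  class(out) <- c("pw_patient_record", class(out))
  out
}
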