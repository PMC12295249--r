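#' Write a multi-channel recording as delimited text
#'
#' One row per sample: a `time_s` column followed by one column per channel.
#' All channels must share one sampling grid.
#'
#' @param recording A [pw_recording()].
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  df <- as_tibble(recording)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a multi-channel recording from delimited text
#'
#' Expects a strictly increasing `time_s` column on a uniform grid (relative
#' deviations of the time step beyond 1% are rejected) and one column per
#' channel. Column names are mapped to channel kinds through `schema`.
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping file column names to channel
#'   kinds; the default expects columns named like the kinds themselves.
#' @param require Channels that must be present (default: ECG plus the three
#'   pulse channels found in the file header; set to `character()` to accept
#'   any subset).
#' @return A [pw_recording()].
#' @export
read_recording <- function(path,
                           schema = c(ecg = "ecg", cap = "cap",
                                      rap = "rap", ebi = "ebi"),
                           require = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist.", path),
          class = "pk_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(df)) {
    abort("recording file must contain a `time_s` column.",
          class = "pk_format_error")
  }
  tt <- df$time_s
  dt <- diff(tt)
  if (any(dt <= 0)) {
    abort("`time_s` must be strictly increasing (duplicate or non-monotone timestamps).",
          class = "pk_format_error")
  }
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step) {
    abort("non-uniform time steps beyond 1% relative tolerance.",
          class = "pk_format_error")
  }
  fs <- 1 / step
  present <- intersect(names(schema), names(df))
  need <- require %||% intersect(names(schema), names(df))
  missing <- setdiff(need, names(df))
  if (length(missing) || !length(present)) {
    abort(sprintf("missing channel column(s): %s.",
                  paste(if (length(missing)) missing else names(schema),
                        collapse = ", ")),
          class = "pk_missing_channel")
  }
  traces <- list()
  for (col in present) {
    kind <- schema[[col]]
    traces[[kind]] <- pw_trace(df[[col]], fs = fs, t0 = tt[1], kind = kind)
  }
  pw_recording(traces, patient_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write ground truth or patient records as JSON
#'
#' @param x A `pw_ground_truth`, [patient_record()] row, or any list/tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  if (inherits(x, "pw_ground_truth")) {
    x <- x[setdiff(names(x), "config")]
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

FEATURE_COLUMNS <- c("patient_id", "n_beats", "rb_delay_ebi_s",
                     "rb_delay_rap_s", "rb_delay_cap_s", "pat_ebi_s",
                     "pat_rap_s", "pat_cap_s", "ptt_s", "pwv_mps",
                     "cpwv_mps")

#' Write and read per-patient feature tables
#'
#' Delimited text with one row per patient and a documented column order
#' (`patient_id`, beat count, per-channel R-B delays, arrival times, transit
#' time, velocities, then any extra columns). Missing values are written as
#' empty fields, never as zeros.
#'
#' @param features Tibble of patient features, e.g. rows from
#'   [build_patient_features()].
#' @param path CSV file path.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_features <- function(features, path) {
  if (!is.data.frame(features) || nrow(features) == 0) {
    abort("`features` must be a non-empty data frame.",
          class = "pk_invalid_input")
  }
  lead <- intersect(FEATURE_COLUMNS, names(features))
  rest <- setdiff(names(features), lead)
  readr::write_csv(features[, c(lead, rest)], path, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}
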