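# Plain-text import/export: stream CSVs with JSON truth sidecars,
# calibration tables, event records, manager records.

#' Export a stream as CSV plus a JSON truth sidecar
#'
#' Writes one column per channel plus a time column; the embedded ground
#' truth goes to `<path>.truth.json`.
#'
#' @param stream a `ppg_stream` or `ecg_stream`.
#' @param path CSV file path.
#' @return invisibly, the paths written.
#' @export
write_stream_csv <- function(stream, path) {
  if (inherits(stream, "ppg_stream")) {
    n <- length(stream$red)
    df <- data.frame(time_s = (seq_len(n) - 1) / stream$fs_hz,
                     red = stream$red, ir = stream$ir)
  } else if (inherits(stream, "ecg_stream")) {
    n <- ncol(stream$leads8)
    df <- data.frame(time_s = (seq_len(n) - 1) / stream$fs_hz,
                     t(stream$leads8),
                     lead_off = stream$lead_off_status)
  } else stopf("unsupported stream class")
  utils::write.csv(df, path, row.names = FALSE)
  truth_path <- paste0(path, ".truth.json")
  jsonlite::write_json(stream$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, truth_path))
}

#' Load / save an SpO2 calibration table
#'
#' Two-column CSV (`ratio`, `spo2`); the ratio column must be increasing
#' and the spo2 column non-increasing.
#'
#' @param path CSV file path.
#' @return `read_spo2_lut`: a calibration data frame usable by
#'   [calibrate()].
#' @export
read_spo2_lut <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("ratio", "spo2") %in% names(df)))
    stopf("calibration CSV needs 'ratio' and 'spo2' columns")
  df <- df[order(df$ratio), c("ratio", "spo2")]
  if (any(diff(df$spo2) > 0))
    stopf("calibration must be monotonically non-increasing in ratio")
  df
}

#' @rdname read_spo2_lut
#' @param lut a calibration data frame.
#' @export
write_spo2_lut <- function(lut, path) {
  utils::write.csv(lut[, c("ratio", "spo2")], path, row.names = FALSE)
  invisible(path)
}

#' Export an event record
#'
#' JSON for the structured part (warning, per-entry heart rate, lead
#' status, R-R intervals) and a waveform CSV concatenating the lead-II
#' segments.
#'
#' @param record an `event_record`.
#' @param json_path,csv_path output paths.
#' @return invisibly, the paths written.
#' @export
write_event_record <- function(record, json_path, csv_path) {
  stopifnot(inherits(record, "event_record"))
  entries <- lapply(record$entries, function(e)
    list(hr_bpm = e$hr_bpm, lead_off_status = e$lead_off_status,
         timestamp = e$timestamp, rr_last5_ms = e$rr_last5_ms,
         n_samples = length(e$lead_ii_samples)))
  jsonlite::write_json(
    list(warning = list(kind = record$warning$kind,
                        timestamp = record$warning$timestamp,
                        value = record$warning$value),
         start_s = record$start_s, end_s = record$end_s,
         entries = entries),
    json_path, auto_unbox = TRUE, digits = NA)
  wave <- unlist(lapply(record$entries, `[[`, "lead_ii_samples"))
  utils::write.csv(data.frame(lead_ii_mv = wave), csv_path,
                   row.names = FALSE)
  invisible(c(json_path, csv_path))
}

#' Write the manager record as JSON lines
#'
#' One JSON object per received measurement or warning:
#' `{time, kind, value, units}`.
#'
#' @param record a manager record (from a [run_session()] result).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_manager_record <- function(record, path) {
  units_of <- c(spo2_pct = "%", pulse_bpm = "bpm", hr_bpm = "bpm",
                unknown = "")
  con <- file(path, "w")
  on.exit(close(con))
  m <- record$measurements
  for (i in seq_len(nrow(m))) {
    writeLines(jsonlite::toJSON(
      list(time = m$time[i], kind = m$kind[i], value = m$value[i],
           units = unname(units_of[m$kind[i]])),
      auto_unbox = TRUE, digits = NA), con)
  }
  for (w in record$warnings) {
    writeLines(jsonlite::toJSON(
      list(time = w$timestamp, kind = paste0("warning:", w$kind),
           value = w$value,
           units = if (w$kind == "desaturation") "%" else "bpm"),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write a session log as JSON
#'
#' @param session_log ordered transition list from [run_session()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_session_log <- function(session_log, path) {
  jsonlite::write_json(session_log, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
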