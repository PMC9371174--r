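# Manager session: association handling, configuration learning, and the
# received-data record.

#' Create a manager session
#'
#' The manager knows the standard pulse-oximeter configuration a priori;
#' extended configurations must be learned through a configuration-report
#' exchange before their data reports are understood.
#'
#' @return a list of class `manager_session`: `state` (`idle`,
#'   `configuring`, `associated`), `known_config_ids`, `learned_configs`,
#'   `record` (measurements, warnings, waveform samples), and a `log`.
#' @export
manager_session <- function() {
  structure(list(state = "idle",
                 known_config_ids = standard_config("pulse_oximeter_10404")$config_id,
                 learned_configs = list(),
                 pending_config_id = NULL,
                 record = list(
                   measurements = data.frame(time = numeric(0),
                                             kind = character(0),
                                             value = numeric(0),
                                             stringsAsFactors = FALSE),
                   warnings = list(),
                   ecg_entries = list(),
                   stream_samples = numeric(0),
                   stream_seqs = integer(0)),
                 log = list()),
            class = "manager_session")
}

mgr_log <- function(mgr, t_s, state_before, event, apdu_kind) {
  mgr$log[[length(mgr$log) + 1L]] <- list(
    time = t_s, direction = "manager", state_before = state_before,
    event = event, state_after = mgr$state, apdu_kind = apdu_kind)
  mgr
}

#' Step the manager with a received APDU
#'
#' Association requests carrying a standard (or previously learned)
#' configuration are accepted outright; an unknown extended configuration
#' is accepted pending its configuration report. Reliable data reports are
#' decoded into the record and acknowledged; streaming reports are
#' appended. A data report outside an association triggers an abort.
#'
#' @param mgr a [manager_session()].
#' @param a an [apdu()].
#' @param t_s simulated receive time.
#' @return list with `mgr` (updated) and `actions` (APDUs to send back).
#' @export
manager_step <- function(mgr, a, t_s = NA_real_) {
  stopifnot(inherits(mgr, "manager_session"), inherits(a, "apdu"))
  st <- mgr$state
  actions <- list()
  switch(
    a$kind,
    assoc_request = {
      cfg <- a$config
      if (cfg$standard || cfg$config_id %in% mgr$known_config_ids ||
          !is.null(mgr$learned_configs[[as.character(cfg$config_id)]])) {
        mgr$state <- "associated"
        actions <- list(apdu("assoc_response", result = "accepted"))
      } else {
        mgr$state <- "configuring"
        mgr$pending_config_id <- cfg$config_id
        actions <- list(apdu("assoc_response",
                             result = "accepted_unknown_config"))
      }
    },
    config_report = {
      if (st != "configuring") {
        actions <- list(apdu("config_response", config_id = a$config$config_id,
                             result = "rejected"))
      } else {
        mgr$learned_configs[[as.character(a$config$config_id)]] <- a$config
        mgr$pending_config_id <- NULL
        mgr$state <- "associated"
        actions <- list(apdu("config_response", config_id = a$config$config_id,
                             result = "accepted"))
      }
    },
    data_report_reliable = {
      if (st != "associated") {
        actions <- list(apdu("assoc_response", result = "rejected"))
        mgr <- mgr_log(mgr, t_s, st, "abort:data_before_association", a$kind)
        return(list(mgr = mgr, actions = actions))
      }
      if (!is.null(a$ecg_entry)) {
        e <- a$ecg_entry
        mgr$record$ecg_entries[[length(mgr$record$ecg_entries) + 1L]] <-
          c(e, list(timestamp_s = a$timestamp_s, seq = a$seq))
        mgr$record$measurements <- rbind(
          mgr$record$measurements,
          data.frame(time = a$timestamp_s, kind = "hr_bpm",
                     value = e$hr_bpm, stringsAsFactors = FALSE))
      } else if (!is.null(a$observations) && nrow(a$observations) > 0) {
        obs <- a$observations
        kinds <- ifelse(obs$handle == 1L, "spo2_pct",
                        ifelse(obs$handle == 10L, "pulse_bpm", "unknown"))
        mgr$record$measurements <- rbind(
          mgr$record$measurements,
          data.frame(time = a$timestamp_s, kind = kinds,
                     value = obs$mantissa * 10^obs$exponent,
                     stringsAsFactors = FALSE))
      }
      actions <- list(apdu("ack", seq = a$seq))
    },
    data_report_streaming = {
      if (st != "associated") {
        actions <- list(apdu("assoc_response", result = "rejected"))
        mgr <- mgr_log(mgr, t_s, st, "abort:data_before_association", a$kind)
        return(list(mgr = mgr, actions = actions))
      }
      mgr$record$stream_samples <- c(mgr$record$stream_samples, a$samples)
      mgr$record$stream_seqs <- c(mgr$record$stream_seqs, a$seq)
    },
    release_request = {
      mgr$state <- "idle"
      actions <- list(apdu("release_response"))
    },
    stopf("manager cannot handle APDU kind: %s", a$kind)
  )
  mgr <- mgr_log(mgr, t_s, st, a$kind,
                 if (length(actions)) actions[[1]]$kind else NA_character_)
  list(mgr = mgr, actions = actions)
}

#' Record an iWrap textual update at the manager
#'
#' The pulse-oximeter agent reports over the textual dialect; the manager
#' parses value lines into measurements (timestamp lines update the pending
#' measurement time).
#'
#' @param mgr a [manager_session()].
#' @param line a serialized iWrap command line.
#' @param t_s receive time (used when no timestamp line follows).
#' @return list with `mgr` and `ack` (logical: a textual ACK is returned
#'   for value lines).
#' @export
manager_handle_iwrap <- function(mgr, line, t_s = NA_real_) {
  cmd <- parse_iwrap_command(line)
  if (cmd$attr_id == IWRAP[["attr_value"]]) {
    v <- parse_iwrap_value(cmd$value)
    kind <- if (cmd$obj_handle == IWRAP[["handle_spo2"]]) "spo2_pct"
            else if (cmd$obj_handle == IWRAP[["handle_pulse"]]) "pulse_bpm"
            else "unknown"
    mgr$record$measurements <- rbind(
      mgr$record$measurements,
      data.frame(time = t_s, kind = kind, value = v$value,
                 stringsAsFactors = FALSE))
    mgr <- mgr_log(mgr, t_s, mgr$state, "iwrap_update", "ack")
    return(list(mgr = mgr, ack = TRUE))
  }
  mgr <- mgr_log(mgr, t_s, mgr$state, "iwrap_timestamp", NA_character_)
  list(mgr = mgr, ack = FALSE)
}
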