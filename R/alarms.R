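# Alarm engine: desaturation and rate warnings, pre-event ring buffer,
# event-record extraction.

#' Alarm configuration
#'
#' Defaults follow the monitoring rules of the modelled device: a
#' desaturation warning when the running mean of the last 10 SpO2 values
#' falls below 95% (the first four values of a session are discarded as
#' warm-up), bradycardia below 60 bpm, tachycardia above 100 bpm (both
#' strict inequalities), and event records spanning five minutes before and
#' after the warning.
#'
#' @param spo2_threshold_pct desaturation threshold, percent.
#' @param spo2_mean_window running-mean length, values.
#' @param spo2_warmup_discard values discarded at session start.
#' @param brady_bpm,tachy_bpm rate bounds, bpm (`brady_bpm < tachy_bpm`).
#' @param pre_event_s,post_event_s event-record span, seconds.
#' @return an object of class `alarm_config`.
#' @export
alarm_config <- function(spo2_threshold_pct = 95, spo2_mean_window = 10,
                         spo2_warmup_discard = 4, brady_bpm = 60,
                         tachy_bpm = 100, pre_event_s = 300,
                         post_event_s = 300) {
  vals <- c(spo2_threshold_pct, spo2_mean_window, brady_bpm, tachy_bpm,
            pre_event_s, post_event_s)
  if (any(vals <= 0) || spo2_warmup_discard < 0)
    stopf("alarm config values must be positive")
  if (brady_bpm >= tachy_bpm) stopf("brady_bpm must be below tachy_bpm")
  structure(list(spo2_threshold_pct = spo2_threshold_pct,
                 spo2_mean_window = spo2_mean_window,
                 spo2_warmup_discard = spo2_warmup_discard,
                 brady_bpm = brady_bpm, tachy_bpm = tachy_bpm,
                 pre_event_s = pre_event_s, post_event_s = post_event_s),
            class = "alarm_config")
}

new_warning <- function(kind, timestamp, value) {
  structure(list(kind = kind, timestamp = timestamp, value = value,
                 acknowledged = FALSE),
            class = "phd_warning")
}

#' Fresh SpO2 alarm state
#' @param cfg an [alarm_config()].
#' @return opaque state for [spo2_alarm_step()].
#' @export
spo2_alarm_state <- function(cfg = alarm_config()) {
  list(seen = 0L, values = numeric(0), armed = TRUE)
}

#' Step the desaturation alarm
#'
#' The first `spo2_warmup_discard` values of a session are dropped;
#' evaluation happens only once a full window of `spo2_mean_window`
#' post-warm-up values exists. A warning fires when the window mean falls
#' strictly below the threshold; the alarm is edge-triggered and re-arms
#' only after the mean returns to or above the threshold.
#'
#' @param state from [spo2_alarm_state()] or a previous step.
#' @param new_value SpO2 percentage in \[0, 100\].
#' @param cfg an [alarm_config()].
#' @param t_s timestamp attached to any warning.
#' @return list with `state` (updated) and `warning` (`NULL` or a warning
#'   object with `kind`, `timestamp`, `value`, `acknowledged`).
#' @export
spo2_alarm_step <- function(state, new_value, cfg = alarm_config(),
                            t_s = NA_real_) {
  if (!is.finite(new_value) || new_value < 0 || new_value > 100)
    stopf("SpO2 value outside [0, 100]: %s", format(new_value))
  state$seen <- state$seen + 1L
  if (state$seen <= cfg$spo2_warmup_discard)
    return(list(state = state, warning = NULL))
  state$values <- c(state$values, new_value)
  keep <- cfg$spo2_mean_window
  if (length(state$values) > keep)
    state$values <- utils::tail(state$values, keep)
  warning_out <- NULL
  if (length(state$values) >= keep) {
    m <- mean(state$values)
    if (m < cfg$spo2_threshold_pct) {
      if (state$armed) {
        warning_out <- new_warning("desaturation", t_s, new_value)
        state$armed <- FALSE
      }
    } else {
      state$armed <- TRUE
    }
  }
  list(state = state, warning = warning_out)
}

#' Fresh heart-rate alarm state
#' @return opaque state for [hr_alarm_step()].
#' @export
hr_alarm_state <- function() {
  list(armed_brady = TRUE, armed_tachy = TRUE)
}

#' Step the bradycardia/tachycardia alarm
#'
#' Bradycardia fires iff `hr < brady_bpm`; tachycardia iff
#' `hr > tachy_bpm`. Both bounds are strict, so 60 and 100 bpm are normal.
#' Each alarm is edge-triggered and re-arms once the rate returns to the
#' normal side of its bound.
#'
#' @param state from [hr_alarm_state()] or a previous step.
#' @param hr_bpm non-negative integer heart rate.
#' @param cfg an [alarm_config()].
#' @param t_s timestamp attached to any warning.
#' @return list with `state` and `warning` (`NULL` or a warning object).
#' @export
hr_alarm_step <- function(state, hr_bpm, cfg = alarm_config(),
                          t_s = NA_real_) {
  if (hr_bpm < 0) stopf("hr_bpm must be non-negative")
  warning_out <- NULL
  if (hr_bpm < cfg$brady_bpm) {
    if (state$armed_brady) {
      warning_out <- new_warning("bradycardia", t_s, hr_bpm)
      state$armed_brady <- FALSE
    }
  } else {
    state$armed_brady <- TRUE
  }
  if (hr_bpm > cfg$tachy_bpm) {
    if (is.null(warning_out) && state$armed_tachy) {
      warning_out <- new_warning("tachycardia", t_s, hr_bpm)
    }
    state$armed_tachy <- FALSE
  } else {
    state$armed_tachy <- TRUE
  }
  list(state = state, warning = warning_out)
}

#' ECG buffer entry
#'
#' One stored record of the pre-event buffer: the heart rate, lead-off
#' status and timestamp at a detection, the previous five R-R intervals,
#' and the lead-II samples acquired since the previous entry.
#'
#' @param hr_bpm integer heart rate (entries with 0 are never stored).
#' @param lead_off_status integer lead status code.
#' @param timestamp seconds from session start.
#' @param rr_last5_ms five R-R intervals, ms.
#' @param lead_ii_samples numeric samples since the previous entry.
#' @return an object of class `ecg_buffer_entry`.
#' @export
ecg_buffer_entry <- function(hr_bpm, lead_off_status, timestamp,
                             rr_last5_ms, lead_ii_samples) {
  if (length(rr_last5_ms) != 5) stopf("rr_last5_ms must hold five intervals")
  structure(list(hr_bpm = as.integer(hr_bpm),
                 lead_off_status = as.integer(lead_off_status),
                 timestamp = timestamp, rr_last5_ms = rr_last5_ms,
                 lead_ii_samples = lead_ii_samples),
            class = "ecg_buffer_entry")
}

#' Store an entry in the pre-event ring buffer
#'
#' Entries with a zero heart rate are ignored; entries older than
#' `pre_event_s` relative to the newest timestamp are evicted, so the
#' buffer never spans more than the configured pre-event window.
#'
#' @param buffer a list of `ecg_buffer_entry` (possibly empty).
#' @param entry an [ecg_buffer_entry()].
#' @param cfg an [alarm_config()].
#' @return the updated buffer.
#' @export
ring_store <- function(buffer, entry, cfg = alarm_config()) {
  stopifnot(inherits(entry, "ecg_buffer_entry"))
  if (entry$hr_bpm == 0L) return(buffer)
  buffer[[length(buffer) + 1L]] <- entry
  newest <- entry$timestamp
  keep <- vapply(buffer, function(e) e$timestamp > newest - cfg$pre_event_s,
                 logical(1))
  buffer[keep]
}

#' Extract an event record around a warning
#'
#' The record spans `[max(0, t_event - pre_event_s), t_event]` -- from five
#' minutes before the warning, or from the start of the session when the
#' warning comes earlier than that. Entries arriving after the warning are
#' appended live with [event_record_append()] up to
#' `t_event + post_event_s`, completing the (at least) ten-minute record.
#'
#' @param buffer the ring buffer at warning time.
#' @param warning a warning object (as produced by the alarm steps).
#' @param cfg an [alarm_config()].
#' @return an object of class `event_record` with `warning`, `entries`,
#'   `start_s`, `end_s`.
#' @export
extract_event <- function(buffer, warning, cfg = alarm_config()) {
  t_event <- warning$timestamp
  start_s <- max(0, t_event - cfg$pre_event_s)
  keep <- vapply(buffer, function(e)
    e$timestamp >= start_s && e$timestamp <= t_event, logical(1))
  structure(list(warning = warning,
                 entries = buffer[keep],
                 start_s = start_s,
                 end_s = t_event + cfg$post_event_s),
            class = "event_record")
}

#' @rdname extract_event
#' @param record an `event_record`.
#' @param entry an [ecg_buffer_entry()] arriving after the warning.
#' @export
event_record_append <- function(record, entry, cfg = alarm_config()) {
  stopifnot(inherits(record, "event_record"))
  if (entry$hr_bpm == 0L) return(record)
  if (entry$timestamp <= record$warning$timestamp ||
      entry$timestamp > record$end_s) return(record)
  record$entries[[length(record$entries) + 1L]] <- entry
  record
}
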