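# Session orchestration: alarm delivery, event-record packetization, and the
# full generate -> process -> alarm -> transmit -> manager pipeline.

#' Split samples into streaming packets
#'
#' All non-final packets carry exactly `size` samples; a final partial
#' packet flushes the remainder, so every sample appears in exactly one
#' packet, in order.
#'
#' @param samples numeric vector.
#' @param seq0 sequence number of the first packet.
#' @param size samples per full packet (default 20).
#' @return list of `stream_packet` objects (`seq`, `samples`).
#' @export
make_stream_packets <- function(samples, seq0 = 0L, size = 20L) {
  n <- length(samples)
  if (n == 0) return(list())
  starts <- seq(1L, n, by = size)
  lapply(seq_along(starts), function(i) {
    i0 <- starts[i]; i1 <- min(n, i0 + size - 1L)
    structure(list(seq = seq0 + i - 1L, samples = samples[i0:i1]),
              class = "stream_packet")
  })
}

#' Deliver an SpO2 warning over the reliable channel
#'
#' Sends the last SpO2 value and its timestamp as iWrap update lines, then
#' waits for the manager's ACK. If the manager is unreachable the send is
#' retried once after the ACK timeout before a delivery failure is
#' surfaced.
#'
#' @param session a running session, as built by [run_session()]; must hold
#'   an operating agent.
#' @param warning a warning object (from [spo2_alarm_step()]).
#' @param ack_timeout_s simulated ACK timeout (bookkeeping only; the
#'   simulated clock advances by this much per failed attempt).
#' @return list with `delivered` (logical), `attempts`, and the updated
#'   `session`.
#' @export
send_alarm_spo2 <- function(session, warning, ack_timeout_s = 5) {
  stopifnot(inherits(session, "phd_session"))
  if (session$agent$state != "operating") {
    session$pending_alarms[[length(session$pending_alarms) + 1L]] <- warning
    return(list(delivered = FALSE, attempts = 0L, session = session,
                queued = TRUE))
  }
  lines <- build_iwrap_update(warning$value, "spo2",
                              time = session$epoch + warning$timestamp)
  attempts <- 0L
  delivered <- FALSE
  while (attempts < 2L && !delivered) {
    attempts <- attempts + 1L
    for (ln in lines) chan_send(session$wiring$reliable, ln)
    if (session$wiring$manager_alive) {
      while (chan_length(session$wiring$reliable) > 0) {
        ln <- chan_receive(session$wiring$reliable)
        res <- manager_handle_iwrap(session$manager, ln,
                                    t_s = warning$timestamp)
        session$manager <- res$mgr
        if (res$ack) delivered <- TRUE
      }
    } else {
      # no manager: messages stay undelivered past the timeout
      session$clock <- session$clock + ack_timeout_s
      session$wiring$reliable$queue <- list()
    }
  }
  if (delivered) {
    warning$acknowledged <- TRUE
    session$manager$record$warnings[[
      length(session$manager$record$warnings) + 1L]] <- warning
  }
  list(delivered = delivered, attempts = attempts, session = session)
}

#' Transmit an event record
#'
#' For each buffer entry one reliable packet is sent (heart rate, lead-off
#' status, the five previous R-R intervals, and the timestamp), followed by
#' streaming packets of 20 lead-II samples covering that entry's waveform
#' segment; a final partial packet flushes any remainder before the next
#' reliable packet begins. Every reliable packet is acknowledged by the
#' manager.
#'
#' @param session a `phd_session` with an operating ECG agent.
#' @param record an [extract_event()] record.
#' @return list with `session`, `n_reliable`, `n_streaming`.
#' @export
transmit_event <- function(session, record) {
  stopifnot(inherits(session, "phd_session"), inherits(record, "event_record"))
  if (session$agent$state != "operating")
    stopf("agent must be operating to transmit an event record")
  n_rel <- 0L; n_str <- 0L
  for (e in record$entries) {
    rel <- apdu("data_report_reliable", seq = session$seq_reliable,
                timestamp_s = e$timestamp,
                ecg_entry = list(hr_bpm = as.integer(e$hr_bpm),
                                 lead_off_status = as.integer(e$lead_off_status),
                                 rr_last5_ms = as.integer(round(e$rr_last5_ms))))
    session$seq_reliable <- session$seq_reliable + 1L
    chan_send(session$wiring$reliable, encode_apdu(rel))
    n_rel <- n_rel + 1L
    pkts <- make_stream_packets(e$lead_ii_samples, seq0 = session$seq_streaming)
    session$seq_streaming <- session$seq_streaming + length(pkts)
    for (p in pkts) {
      chan_send(session$wiring$streaming,
                encode_apdu(apdu("data_report_streaming", seq = p$seq,
                                 samples = p$samples)))
      n_str <- n_str + 1L
    }
    session <- pump_manager(session)
  }
  list(session = session, n_reliable = n_rel, n_streaming = n_str)
}

# drain both agent->manager channels through the manager, routing manager
# actions (acks, responses) back over the control channel to the agent
pump_manager <- function(session) {
  if (!session$wiring$manager_alive) return(session)
  repeat {
    msg <- chan_receive(session$wiring$reliable)
    if (is.null(msg)) break
    res <- manager_step(session$manager, decode_apdu(msg), t_s = session$clock)
    session$manager <- res$mgr
    for (act in res$actions) {
      if (act$kind == "ack") {
        session$acks_received <- session$acks_received + 1L
        session$wiring$reliable$acked <- session$wiring$reliable$acked + 1L
      } else {
        chan_send(session$wiring$control, encode_apdu(act))
      }
    }
  }
  repeat {
    msg <- chan_receive(session$wiring$streaming)
    if (is.null(msg)) break
    res <- manager_step(session$manager, decode_apdu(msg), t_s = session$clock)
    session$manager <- res$mgr
  }
  session
}

new_session <- function(scenario, wiring, cfg, epoch) {
  config <- standard_config(if (scenario$kind == "ppg")
    "pulse_oximeter_10404" else "basic_ecg_10406")
  structure(list(scenario = scenario, wiring = wiring,
                 agent = agent_session(config),
                 manager = manager_session(),
                 cfg = cfg, clock = 0, epoch = epoch,
                 seq_reliable = 0L, seq_streaming = 0L,
                 acks_received = 0L, pending_alarms = list(),
                 warnings = list(), log = list()),
            class = "phd_session")
}

# run the association sequence: connect -> assoc_request -> assoc_response
# (-> config exchange for extended configs) -> operating
associate <- function(session) {
  res <- agent_step(session$agent, list(type = "connect"), t_s = session$clock)
  session$agent <- res$agent
  for (act in res$actions) chan_send(session$wiring$reliable, encode_apdu(act))
  guard <- 0L
  while (session$agent$state != "operating" && guard < 8L) {
    guard <- guard + 1L
    repeat {
      msg <- chan_receive(session$wiring$reliable)
      if (is.null(msg)) break
      mres <- manager_step(session$manager, decode_apdu(msg),
                           t_s = session$clock)
      session$manager <- mres$mgr
      for (act in mres$actions) chan_send(session$wiring$control,
                                          encode_apdu(act))
    }
    msg <- chan_receive(session$wiring$control)
    if (is.null(msg)) break
    a <- decode_apdu(msg)
    ev <- if (a$kind == "assoc_response")
      list(type = "assoc_response", result = a$result)
    else if (a$kind == "config_response")
      list(type = "config_response", result = a$result)
    else NULL
    if (is.null(ev)) next
    ares <- agent_step(session$agent, ev, t_s = session$clock)
    session$agent <- ares$agent
    for (act in ares$actions) chan_send(session$wiring$reliable,
                                        encode_apdu(act))
  }
  session
}

#' Run a full telemonitoring session on a scenario
#'
#' The complete pipeline: the scenario's stream is processed by the signal
#' chain (SpO2 pipeline for PPG scenarios; filtering, QRS detection and
#' heart-rate computation for ECG scenarios), alarm rules are evaluated in
#' time order, measurements are reported to the manager (iWrap lines for
#' the pulse-oximeter agent, binary APDUs for the ECG agent), and any
#' heart-rate warning triggers extraction and transmission of the
#' ten-minute event record. Deterministic for a fixed scenario seed.
#'
#' @param scenario a [make_scenario()] result (or a scenario name).
#' @param wiring a [make_wiring()] transport (a fresh loopback by default).
#' @param cfg an [alarm_config()].
#' @param seed seed used when `scenario` is given as a name.
#' @param periodic_reports send every measurement (not only alarms) while
#'   associated.
#' @return a list of class `phd_session_result`: `record` (what the manager
#'   received), `warnings` (emitted by the alarm engine), `session_log`
#'   (agent + manager transition history, ordered), `measurements` (the
#'   agent-side series), and `session` internals.
#' @export
run_session <- function(scenario, wiring = NULL, cfg = alarm_config(),
                        seed = 1L, periodic_reports = TRUE) {
  if (is.character(scenario)) scenario <- make_scenario(scenario, seed)
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(wiring)) wiring <- make_wiring()
  epoch <- as.POSIXct("2013-01-30 20:00:00", tz = "UTC")
  session <- new_session(scenario, wiring, cfg, epoch)
  session <- associate(session)

  if (scenario$kind == "ppg") {
    session <- run_spo2_session(session, periodic_reports)
  } else {
    session <- run_ecg_session(session)
  }

  log <- c(session$agent$log, session$manager$log)
  ord <- order(vapply(log, function(e)
    if (is.null(e$time) || is.na(e$time)) 0 else e$time, numeric(1)))
  structure(list(record = session$manager$record,
                 warnings = session$warnings,
                 session_log = log[ord],
                 measurements = session$measurements,
                 session = session),
            class = "phd_session_result")
}

run_spo2_session <- function(session, periodic_reports) {
  meas <- process_ppg(session$scenario$stream)
  session$measurements <- meas
  st <- spo2_alarm_state(session$cfg)
  for (i in seq_len(nrow(meas))) {
    session$clock <- meas$t_s[i]
    step <- spo2_alarm_step(st, meas$spo2_pct[i], session$cfg,
                            t_s = meas$t_s[i])
    st <- step$state
    if (periodic_reports && session$agent$state == "operating") {
      for (ln in c(build_iwrap_update(round(meas$spo2_pct[i]), "spo2",
                                      time = session$epoch + meas$t_s[i]),
                   build_iwrap_update(round(meas$pulse_bpm[i]), "pulse")))
        chan_send(session$wiring$reliable, ln)
      while (chan_length(session$wiring$reliable) > 0) {
        ln <- chan_receive(session$wiring$reliable)
        res <- manager_handle_iwrap(session$manager, ln, t_s = meas$t_s[i])
        session$manager <- res$mgr
      }
    }
    if (!is.null(step$warning)) {
      session$warnings[[length(session$warnings) + 1L]] <- step$warning
      out <- send_alarm_spo2(session, step$warning)
      session <- out$session
    }
  }
  session
}

run_ecg_session <- function(session) {
  stream <- session$scenario$stream
  fs <- stream$fs_hz
  lead2_raw <- stream$leads8[2, ]
  lead2 <- notch_filter(dc_block(lead2_raw), stream$spec$mains_hz, fs)
  rr <- detect_qrs(lead2, fs)
  hrs <- hr_series(rr)
  session$measurements <- data.frame(
    t_s = vapply(hrs, `[[`, numeric(1), "t_s"),
    hr_bpm = vapply(hrs, function(h) as.numeric(h$hr_bpm), numeric(1)))

  st <- hr_alarm_state()
  buffer <- list()
  records <- list()
  prev_idx <- 1L
  for (h in hrs) {
    session$clock <- h$t_s
    idx <- round(h$t_s * fs) + 1L
    entry <- ecg_buffer_entry(
      hr_bpm = h$hr_bpm,
      lead_off_status = stream$lead_off_status[min(idx, length(lead2_raw))],
      timestamp = h$t_s, rr_last5_ms = h$rr_last5_ms,
      lead_ii_samples = lead2_raw[prev_idx:min(idx, length(lead2_raw))])
    prev_idx <- min(idx, length(lead2_raw)) + 1L
    buffer <- ring_store(buffer, entry, session$cfg)
    for (k in seq_along(records)) {
      records[[k]] <- event_record_append(records[[k]], entry, session$cfg)
    }
    step <- hr_alarm_step(st, h$hr_bpm, session$cfg, t_s = h$t_s)
    st <- step$state
    if (!is.null(step$warning)) {
      session$warnings[[length(session$warnings) + 1L]] <- step$warning
      session$manager$record$warnings[[
        length(session$manager$record$warnings) + 1L]] <- step$warning
      records[[length(records) + 1L]] <- extract_event(buffer, step$warning,
                                                       session$cfg)
    }
  }
  for (rec in records) {
    out <- transmit_event(session, rec)
    session <- out$session
  }
  session$event_records <- records
  session
}
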