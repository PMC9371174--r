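# Agent connection state machine (11073-20601 style).

AGENT_STATES <- c("disconnected", "unassociated", "associating",
                  "configuring", "operating")
AGENT_EVENTS <- c("connect", "assoc_response:accepted",
                  "assoc_response:accepted_unknown_config",
                  "assoc_response:rejected", "config_response:accepted",
                  "config_response:rejected", "disconnect", "release")

#' Create an agent session
#'
#' @param config the agent's [device_config()] (standard or extended).
#' @return a list of class `agent_session`: `state`, `config`,
#'   `active_config` (set on entering operating), and a transition `log`.
#' @export
agent_session <- function(config) {
  stopifnot(inherits(config, "device_config"))
  structure(list(state = "disconnected", config = config,
                 active_config = NULL, log = list()),
            class = "agent_session")
}

agent_event_key <- function(event) {
  if (event$type %in% c("assoc_response", "config_response"))
    paste0(event$type, ":", event$result)
  else event$type
}

#' Step the agent state machine
#'
#' Deterministic transition table. `connect` starts association (the agent
#' emits its association request); an accepted response with a known
#' (standard) configuration enters `operating`; acceptance with an unknown
#' configuration enters `configuring` and emits the configuration report; a
#' rejection falls back to `unassociated`. Any undefined (state, event)
#' pair raises a `protocol_violation` condition and leaves the state
#' unchanged.
#'
#' @param agent an [agent_session()].
#' @param event a list with `type` (one of `connect`, `assoc_response`,
#'   `config_response`, `disconnect`, `release`) and, for responses, a
#'   `result` field.
#' @param t_s simulated time for the transition log.
#' @return list with `agent` (updated) and `actions` (a list of [apdu()]s
#'   to emit).
#' @export
agent_step <- function(agent, event, t_s = NA_real_) {
  stopifnot(inherits(agent, "agent_session"))
  key <- agent_event_key(event)
  if (!key %in% AGENT_EVENTS)
    stopf("unknown agent event: %s", key)
  st <- agent$state
  actions <- list()
  new_state <- NULL

  if (key == "disconnect") {
    new_state <- "disconnected"
  } else if (st %in% c("disconnected", "unassociated") && key == "connect") {
    new_state <- "associating"
    actions <- list(apdu("assoc_request", config = agent$config))
  } else if (st %in% c("associating", "unassociated") &&
             key == "assoc_response:accepted") {
    new_state <- "operating"
    agent$active_config <- agent$config
  } else if (st %in% c("associating", "unassociated") &&
             key == "assoc_response:accepted_unknown_config") {
    new_state <- "configuring"
    actions <- list(apdu("config_report", config = agent$config))
  } else if (st %in% c("associating", "unassociated") &&
             key == "assoc_response:rejected") {
    new_state <- "unassociated"
  } else if (st == "configuring" && key == "config_response:accepted") {
    new_state <- "operating"
    agent$active_config <- agent$config
  } else if (st == "configuring" && key == "config_response:rejected") {
    new_state <- "unassociated"
  } else if (st == "operating" && key == "release") {
    new_state <- "unassociated"
    agent$active_config <- NULL
    actions <- list(apdu("release_request"))
  }

  if (is.null(new_state)) {
    cond <- structure(
      class = c("protocol_violation", "error", "condition"),
      list(message = sprintf("protocol violation: event '%s' in state '%s'",
                             key, st),
           call = NULL, state = st, event = key))
    stop(cond)
  }

  agent$log[[length(agent$log) + 1L]] <- list(
    time = t_s, direction = "agent", state_before = st, event = key,
    state_after = new_state,
    apdu_kind = if (length(actions)) actions[[1]]$kind else NA_character_)
  agent$state <- new_state
  list(agent = agent, actions = actions)
}
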