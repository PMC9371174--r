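# In-memory two-channel transport emulating the paired reliable and
# streaming data channels of a health-device link.

#' Create a transport channel
#'
#' An in-order queue of messages. The reliable channel expects every
#' delivered message to be acknowledged exactly once; the streaming channel
#' delivers in order without acknowledgement. Channels are environments, so
#' sends and receives mutate in place.
#'
#' @param kind `"reliable"` or `"streaming"`.
#' @return an environment of class `phd_channel`.
#' @export
channel <- function(kind = c("reliable", "streaming")) {
  kind <- match.arg(kind)
  env <- new.env(parent = emptyenv())
  env$kind <- kind
  env$queue <- list()
  env$delivered <- 0L
  env$acked <- 0L
  env$open <- TRUE
  class(env) <- "phd_channel"
  env
}

#' @rdname channel
#' @param ch a channel.
#' @param msg any message object.
#' @export
chan_send <- function(ch, msg) {
  if (!ch$open) stopf("channel is closed")
  ch$queue[[length(ch$queue) + 1L]] <- msg
  invisible(ch)
}

#' @rdname channel
#' @export
chan_receive <- function(ch) {
  if (length(ch$queue) == 0) return(NULL)
  msg <- ch$queue[[1L]]
  ch$queue <- ch$queue[-1L]
  ch$delivered <- ch$delivered + 1L
  msg
}

#' @rdname channel
#' @export
chan_length <- function(ch) length(ch$queue)

#' Wire an agent to a manager
#'
#' @return a list of class `wiring` with agent-to-manager `reliable` and
#'   `streaming` channels and a manager-to-agent `control` channel, plus a
#'   `manager_alive` flag used to simulate an unreachable manager.
#' @export
make_wiring <- function() {
  structure(list(reliable = channel("reliable"),
                 streaming = channel("streaming"),
                 control = channel("reliable"),
                 manager_alive = TRUE),
            class = "wiring")
}
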