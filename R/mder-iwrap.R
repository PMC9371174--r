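# Textual iWrap-style agent dialect: AGENT UPDATE lines carrying object
# handle, attribute id, and a mantissa/exponent value token.

#' iWrap dialect constants
#'
#' Object handles and attribute ids used by the pulse-oximeter agent:
#' handle `"1"` is the saturation numeric, handle `"A"` (hex, = 10) the
#' pulse-rate numeric; attribute `"A4C"` (0x0A4C = 2636) is the basic
#' numeric observed value and `"990"` the measurement timestamp.
#'
#' @format named character vector.
#' @export
IWRAP <- c(handle_spo2 = "1", handle_pulse = "A",
           attr_value = "A4C", attr_timestamp = "990",
           link_broadcast = "FFFF")

#' Format / parse an iWrap value token
#'
#' The token is the decimal mantissa, an uppercase `E`, and the decimal
#' exponent, with no padding: 97 percent saturation is `"97E0"`.
#'
#' @param mantissa,exponent integers within SFLOAT range
#'   (mantissa \[-2048, 2047\], exponent \[-8, 7\]).
#' @return `format_iwrap_value`: the token string.
#' @export
format_iwrap_value <- function(mantissa, exponent) {
  s <- sfloat(mantissa, exponent)  # range check
  sprintf("%dE%d", s$mantissa, s$exponent)
}

#' @rdname format_iwrap_value
#' @param token a value token such as `"97E0"` or `"5E-1"`.
#' @return `parse_iwrap_value`: list with `mantissa`, `exponent`, `value`.
#' @export
parse_iwrap_value <- function(token) {
  m <- regmatches(token, regexec("^(-?[0-9]+)E(-?[0-9]+)$", token))[[1]]
  if (length(m) != 3)
    stopf("malformed iWrap value token: '%s'", token)
  mantissa <- as.integer(m[2]); exponent <- as.integer(m[3])
  list(mantissa = mantissa, exponent = exponent,
       value = mantissa * 10^exponent)
}

#' Construct / serialize / parse an iWrap command
#'
#' Commands serialize as single-space-separated uppercase tokens:
#' `AGENT UPDATE <link> <handle> <attr> <value>`.
#'
#' @param verb currently only `"AGENT_UPDATE"`.
#' @param link_id hex link token (`"FFFF"` = broadcast to the link).
#' @param obj_handle,attr_id hex tokens, see [IWRAP].
#' @param value value token (mantissa/exponent or a timestamp).
#' @return an object of class `iwrap_command`.
#' @export
iwrap_command <- function(verb = "AGENT_UPDATE", link_id = IWRAP["link_broadcast"],
                          obj_handle, attr_id, value) {
  if (verb != "AGENT_UPDATE") stopf("unknown iWrap verb: %s", verb)
  structure(list(verb = verb, link_id = toupper(as.character(link_id)),
                 obj_handle = toupper(as.character(obj_handle)),
                 attr_id = toupper(as.character(attr_id)),
                 value = as.character(value)),
            class = "iwrap_command")
}

#' @rdname iwrap_command
#' @param cmd an `iwrap_command`.
#' @export
format_iwrap_command <- function(cmd) {
  stopifnot(inherits(cmd, "iwrap_command"))
  paste("AGENT UPDATE", cmd$link_id, cmd$obj_handle, cmd$attr_id, cmd$value)
}

#' @rdname iwrap_command
#' @param line a serialized command line.
#' @export
parse_iwrap_command <- function(line) {
  tok <- strsplit(trimws(line), " +")[[1]]
  if (length(tok) != 6 || tok[1] != "AGENT" || tok[2] != "UPDATE")
    stopf("malformed iWrap command: '%s'", line)
  iwrap_command("AGENT_UPDATE", tok[3], tok[4], tok[5], tok[6])
}

#' Format a measurement timestamp token
#'
#' Internally timestamps are ISO-8601 with a centisecond suffix
#' (`2013-01-30T20:05:26.78`); `compat = TRUE` drops the `.` separator to
#' mirror the legacy on-wire form (`2013-01-30T20:05:2678`).
#'
#' @param time a `POSIXct` time (fractional seconds carried to
#'   centiseconds).
#' @param compat legacy form without the centisecond separator.
#' @return character token.
#' @export
format_iwrap_timestamp <- function(time, compat = FALSE) {
  secs <- as.numeric(time) %% 60
  cs <- round((secs - floor(secs)) * 100)
  base <- format(time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (compat) sprintf("%s%02d", base, cs) else sprintf("%s.%02d", base, cs)
}

#' Build the AGENT UPDATE lines for a measurement
#'
#' Emits the value line (saturation on handle 1, pulse on handle A, both
#' under the observed-value attribute) followed by a timestamp line under
#' attribute 990.
#'
#' @param value numeric measurement value (percent or bpm; sent as an
#'   integer-mantissa token).
#' @param kind `"spo2"` or `"pulse"`.
#' @param time optional `POSIXct` timestamp; when `NULL` only the value
#'   line is returned.
#' @param compat_timestamp use the legacy timestamp form.
#' @return character vector of serialized command lines.
#' @export
build_iwrap_update <- function(value, kind = c("spo2", "pulse"), time = NULL,
                               compat_timestamp = FALSE) {
  kind <- match.arg(kind)
  handle <- if (kind == "spo2") IWRAP[["handle_spo2"]] else IWRAP[["handle_pulse"]]
  s <- as_sfloat(value)
  lines <- format_iwrap_command(iwrap_command(
    "AGENT_UPDATE", IWRAP[["link_broadcast"]], handle,
    IWRAP[["attr_value"]], format_iwrap_value(s$mantissa, s$exponent)))
  if (!is.null(time)) {
    lines <- c(lines, format_iwrap_command(iwrap_command(
      "AGENT_UPDATE", IWRAP[["link_broadcast"]], handle,
      IWRAP[["attr_timestamp"]],
      format_iwrap_timestamp(time, compat = compat_timestamp))))
  }
  lines
}
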