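# Binary APDU framing: big-endian, 16-bit kind tag + 16-bit payload length.
# A self-contained MDER-style dialect covering exactly the message set this
# system exchanges; scalar observations are SFLOAT-coded, waveform samples
# are IEEE-754 float64 so that reassembly is bit-exact.

APDU_KINDS <- c(assoc_request = 0xE200, assoc_response = 0xE300,
                release_request = 0xE400, release_response = 0xE500,
                config_report = 0xE600, config_response = 0xE700,
                data_report_reliable = 0xE800,
                data_report_streaming = 0xE900, ack = 0xEA00)

ASSOC_RESULTS <- c(accepted = 0L, accepted_unknown_config = 1L, rejected = 2L)
CONFIG_RESULTS <- c(accepted = 0L, rejected = 1L)
OBJECT_CLASSES <- c(numeric = 1L, realtime_sample_array = 2L, status = 3L)
SPECIALIZATIONS <- c(pulse_oximeter_10404 = 4100L, basic_ecg_10406 = 4102L)

u16 <- function(x) {
  x <- as.integer(x)
  if (any(x < 0 | x > 65535)) stopf("u16 out of range")
  as.raw(rbind(x %/% 256L, x %% 256L))
}

r_u16 <- function(bytes, at) {
  as.integer(bytes[at]) * 256L + as.integer(bytes[at + 1L])
}

f64 <- function(x) writeBin(as.double(x), raw(), size = 8, endian = "big")

r_f64 <- function(bytes, at, n = 1L) {
  readBin(bytes[at:(at + 8L * n - 1L)], double(), n = n, size = 8,
          endian = "big")
}

#' Construct an APDU
#'
#' One framed protocol message. Payload fields by kind:
#' \describe{
#'   \item{assoc_request}{`config` (a [device_config()]).}
#'   \item{assoc_response}{`result`: `"accepted"`,
#'     `"accepted_unknown_config"`, or `"rejected"`.}
#'   \item{config_report}{`config` (a [device_config()]).}
#'   \item{config_response}{`config_id`, `result` (`"accepted"`/`"rejected"`).}
#'   \item{data_report_reliable}{`seq`, `timestamp_s`, and either
#'     `observations` (data frame `handle`, `mantissa`, `exponent`) or an
#'     `ecg_entry` (`hr_bpm`, `lead_off_status`, `rr_last5_ms`).}
#'   \item{data_report_streaming}{`seq`, `samples` (numeric).}
#'   \item{ack}{`seq`.}
#'   \item{release_request / release_response}{no fields.}
#' }
#'
#' @param kind one of the kinds above.
#' @param ... payload fields.
#' @return an object of class `apdu`.
#' @export
apdu <- function(kind, ...) {
  if (!kind %in% names(APDU_KINDS)) stopf("unknown APDU kind: %s", kind)
  structure(c(list(kind = kind), list(...)), class = "apdu")
}

#' Encode / decode an APDU
#'
#' `decode_apdu(encode_apdu(a))` is the identity for every constructible
#' APDU. Truncated or malformed buffers raise a framing error naming the
#' byte offset.
#'
#' @param a an [apdu()].
#' @return `encode_apdu`: a raw vector; `decode_apdu`: an `apdu`.
#' @export
encode_apdu <- function(a) {
  stopifnot(inherits(a, "apdu"))
  payload <- switch(
    a$kind,
    assoc_request = encode_device_config(a$config),
    assoc_response = u16(ASSOC_RESULTS[[a$result]]),
    release_request = raw(0),
    release_response = raw(0),
    config_report = encode_device_config(a$config),
    config_response = c(u16(a$config_id), u16(CONFIG_RESULTS[[a$result]])),
    data_report_reliable = {
      if (!is.null(a$ecg_entry)) {
        e <- a$ecg_entry
        c(u16(a$seq), as.raw(1L), f64(a$timestamp_s),
          u16(e$hr_bpm), u16(e$lead_off_status),
          u16(round(e$rr_last5_ms)))
      } else {
        obs <- a$observations
        c(u16(a$seq), as.raw(0L), f64(a$timestamp_s), u16(nrow(obs)),
          unlist(lapply(seq_len(nrow(obs)), function(i)
            c(u16(obs$handle[i]),
              encode_sfloat(sfloat(obs$mantissa[i], obs$exponent[i]))))))
      }
    },
    data_report_streaming = c(u16(a$seq), u16(length(a$samples)),
                              f64(a$samples)),
    ack = u16(a$seq)
  )
  c(u16(APDU_KINDS[[a$kind]]), u16(length(payload)), payload)
}

#' @rdname encode_apdu
#' @param bytes a raw vector holding one encoded APDU.
#' @export
decode_apdu <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) < 4)
    stopf("APDU framing error at offset 0: need at least 4 header bytes")
  tag <- r_u16(bytes, 1L)
  kind <- names(APDU_KINDS)[match(tag, APDU_KINDS)]
  if (is.na(kind)) stopf("APDU framing error at offset 0: unknown kind 0x%04X", tag)
  len <- r_u16(bytes, 3L)
  if (length(bytes) < 4L + len)
    stopf("APDU framing error at offset %d: payload truncated", length(bytes))
  p <- bytes[seq_len(len) + 4L]
  switch(
    kind,
    assoc_request = apdu(kind, config = decode_device_config(p)),
    assoc_response = apdu(kind, result = names(ASSOC_RESULTS)[r_u16(p, 1L) + 1L]),
    release_request = apdu(kind),
    release_response = apdu(kind),
    config_report = apdu(kind, config = decode_device_config(p)),
    config_response = apdu(kind, config_id = r_u16(p, 1L),
                           result = names(CONFIG_RESULTS)[r_u16(p, 3L) + 1L]),
    data_report_reliable = {
      seq <- r_u16(p, 1L)
      tagb <- as.integer(p[3L])
      ts <- r_f64(p, 4L)
      if (tagb == 1L) {
        apdu(kind, seq = seq, timestamp_s = ts,
             ecg_entry = list(hr_bpm = r_u16(p, 12L),
                              lead_off_status = r_u16(p, 14L),
                              rr_last5_ms = vapply(0:4, function(i)
                                r_u16(p, 16L + 2L * i), integer(1))))
      } else {
        nobs <- r_u16(p, 12L)
        rows <- lapply(seq_len(nobs), function(i) {
          at <- 14L + (i - 1L) * 4L
          s <- decode_sfloat(p[(at + 2L):(at + 3L)])
          data.frame(handle = r_u16(p, at), mantissa = s$mantissa,
                     exponent = s$exponent)
        })
        obs <- if (nobs > 0) do.call(rbind, rows)
               else data.frame(handle = integer(0), mantissa = integer(0),
                               exponent = integer(0))
        apdu(kind, seq = seq, timestamp_s = ts, observations = obs)
      }
    },
    data_report_streaming = {
      seq <- r_u16(p, 1L)
      ns <- r_u16(p, 3L)
      apdu(kind, seq = seq,
           samples = if (ns > 0) r_f64(p, 5L, ns) else numeric(0))
    },
    ack = apdu(kind, seq = r_u16(p, 1L))
  )
}
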