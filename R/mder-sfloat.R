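# MDER SFLOAT: 16-bit medical float, 4-bit exponent + 12-bit mantissa,
# both two's complement, base 10.

SFLOAT_SPECIALS <- c(NaN. = 0x07FF, PINF = 0x07FE, NINF = 0x0802,
                     NRes = 0x0800, RSVD = 0x0801)

#' Construct an SFLOAT value
#'
#' @param mantissa signed 12-bit integer in \[-2048, 2047\]; the five codes
#'   2046..2047 and -2048..-2046 are reserved for special values and cannot
#'   be used for finite numbers.
#' @param exponent signed 4-bit integer in \[-8, 7\] (power of ten).
#' @param special optional, one of `"NaN"`, `"+INF"`, `"-INF"`, `"NRes"`;
#'   when given, mantissa/exponent are ignored.
#' @return an object of class `sfloat`; its numeric value is
#'   `mantissa * 10^exponent`.
#' @export
sfloat <- function(mantissa = 0L, exponent = 0L, special = NULL) {
  if (!is.null(special)) {
    if (!special %in% c("NaN", "+INF", "-INF", "NRes"))
      stopf("unknown special value: %s", special)
    return(structure(list(mantissa = NA_integer_, exponent = NA_integer_,
                          special = special), class = "sfloat"))
  }
  mantissa <- as.integer(mantissa); exponent <- as.integer(exponent)
  if (mantissa < -2048 || mantissa > 2047)
    stopf("mantissa out of 12-bit range: %d", mantissa)
  if (exponent < -8 || exponent > 7)
    stopf("exponent out of 4-bit range: %d", exponent)
  structure(list(mantissa = mantissa, exponent = exponent, special = NULL),
            class = "sfloat")
}

#' @rdname sfloat
#' @param s an `sfloat`.
#' @export
sfloat_value <- function(s) {
  stopifnot(inherits(s, "sfloat"))
  if (!is.null(s$special))
    return(switch(s$special, "NaN" = NaN, "+INF" = Inf, "-INF" = -Inf,
                  "NRes" = NaN))
  s$mantissa * 10^s$exponent
}

# smallest-exponent SFLOAT representation of a numeric value (exact for
# integers up to 2045; used when packing observations)
as_sfloat <- function(x) {
  if (is.nan(x)) return(sfloat(special = "NaN"))
  if (is.infinite(x)) return(sfloat(special = if (x > 0) "+INF" else "-INF"))
  e <- 0L
  m <- x
  while (e > -8 && m != round(m)) { m <- m * 10; e <- e - 1L }
  m <- round(m)
  while ((m > 2045 || m < -2045) && e < 7) { m <- round(m / 10); e <- e + 1L }
  if (m > 2045 || m < -2045) stopf("value not representable as SFLOAT: %g", x)
  sfloat(as.integer(m), e)
}

#' Encode / decode SFLOAT as two big-endian bytes
#'
#' The high nibble carries the exponent and the low 12 bits the mantissa,
#' both in two's complement. The reserved mantissa codes encode NaN
#' (0x07FF), +INF (0x07FE), -INF (0x0802) and NRes (0x0800);
#' `decode_sfloat(encode_sfloat(s))` is the identity.
#'
#' @param s an [sfloat()].
#' @return `encode_sfloat`: a raw vector of length 2; `decode_sfloat`: an
#'   `sfloat`.
#' @export
encode_sfloat <- function(s) {
  stopifnot(inherits(s, "sfloat"))
  if (!is.null(s$special)) {
    word <- switch(s$special,
                   "NaN" = 0x07FF, "+INF" = 0x07FE,
                   "-INF" = 0x0802, "NRes" = 0x0800)
  } else {
    m12 <- if (s$mantissa < 0) s$mantissa + 4096L else s$mantissa
    if (m12 %in% SFLOAT_SPECIALS && s$exponent == 0L)
      stopf("mantissa %d is a reserved special code", s$mantissa)
    e4 <- if (s$exponent < 0) s$exponent + 16L else s$exponent
    word <- e4 * 4096L + m12
  }
  as.raw(c(word %/% 256L, word %% 256L))
}

#' @rdname encode_sfloat
#' @param bytes a raw vector of length 2 (big-endian).
#' @export
decode_sfloat <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) != 2)
    stopf("SFLOAT must be exactly two bytes")
  word <- as.integer(bytes[1]) * 256L + as.integer(bytes[2])
  if (word == 0x07FF) return(sfloat(special = "NaN"))
  if (word == 0x07FE) return(sfloat(special = "+INF"))
  if (word == 0x0802) return(sfloat(special = "-INF"))
  if (word == 0x0800) return(sfloat(special = "NRes"))
  e4 <- word %/% 4096L
  m12 <- word %% 4096L
  sfloat(if (m12 > 2047L) m12 - 4096L else m12,
         if (e4 > 7L) e4 - 16L else e4)
}
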