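# Wire formats: iWrap textual dialect, SFLOAT, APDU framing, device configs.

test_that("iWrap value tokens format and parse the documented examples", {
  expect_identical(format_iwrap_value(97, 0), "97E0")
  expect_identical(format_iwrap_value(74, 0), "74E0")
  expect_identical(format_iwrap_value(0, 0), "0E0")
  expect_identical(format_iwrap_value(5, -1), "5E-1")
  expect_error(format_iwrap_value(5000, 0), "mantissa")

  expect_equal(parse_iwrap_value("97E0")$value, 97)
  expect_equal(parse_iwrap_value("74E0")$value, 74)
  expect_equal(parse_iwrap_value("5E-1")$value, 0.5)
  expect_error(parse_iwrap_value("97F0"), "97F0")
})

test_that("agent update lines reproduce the documented command strings", {
  t0 <- as.POSIXct("2013-01-30 20:05:26.78", tz = "UTC")
  spo2_lines <- build_iwrap_update(97, "spo2", time = t0,
                                   compat_timestamp = TRUE)
  expect_identical(spo2_lines[1], "AGENT UPDATE FFFF 1 A4C 97E0")
  expect_identical(spo2_lines[2],
                   "AGENT UPDATE FFFF 1 990 2013-01-30T20:05:2678")
  expect_identical(build_iwrap_update(74, "pulse"),
                   "AGENT UPDATE FFFF A A4C 74E0")
  # internal timestamp form keeps the centisecond separator
  expect_match(build_iwrap_update(97, "spo2", time = t0)[2],
               "2013-01-30T20:05:26\\.78$", )
})

test_that("iWrap command lines round-trip through parse", {
  for (line in c("AGENT UPDATE FFFF 1 A4C 97E0",
                 "AGENT UPDATE FFFF A A4C 74E0",
                 "AGENT UPDATE FFFF 1 990 2013-01-30T20:05:2678")) {
    expect_identical(format_iwrap_command(parse_iwrap_command(line)), line)
  }
  m <- parse_iwrap_value(parse_iwrap_command(
    build_iwrap_update(88, "spo2"))$value)
  expect_equal(m$value, 88)
  expect_error(parse_iwrap_command("MANAGER HELLO"), "malformed")
})

test_that("SFLOAT packs to the hand-computed bit layout", {
  expect_identical(encode_sfloat(sfloat(97, 0)), as.raw(c(0x00, 0x61)))
  expect_identical(encode_sfloat(sfloat(0, 0)), as.raw(c(0x00, 0x00)))
  expect_identical(encode_sfloat(sfloat(special = "NaN")),
                   as.raw(c(0x07, 0xFF)))
  # negative mantissa and exponent: cross-check against the arithmetic oracle
  for (case in list(c(-25, 0), c(972, -1), c(-1000, -2), c(2045, 7),
                    c(-2045, -8))) {
    expect_identical(encode_sfloat(sfloat(case[1], case[2])),
                     sfloat_pack_oracle(case[1], case[2]))
  }
  expect_error(encode_sfloat(sfloat(2047, 0)), "reserved")
  expect_error(sfloat(5000, 0), "12-bit")
  expect_error(sfloat(0, 9), "4-bit")
})

test_that("SFLOAT decode inverts encode and preserves numeric value", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(-2045:2045, 1)
    e <- sample(-8:7, 1)
    s <- sfloat(m, e)
    s2 <- decode_sfloat(encode_sfloat(s))
    expect_identical(s2$mantissa, s$mantissa)
    expect_identical(s2$exponent, s$exponent)
    expect_equal(sfloat_value(s2), m * 10^e)
  }
  for (sp in c("NaN", "+INF", "-INF", "NRes")) {
    expect_identical(decode_sfloat(encode_sfloat(sfloat(special = sp)))$special,
                     sp)
  }
  expect_error(decode_sfloat(as.raw(1)), "two bytes")
})

apdu_cases <- function() {
  list(
    apdu("assoc_request", config = standard_config("pulse_oximeter_10404")),
    apdu("assoc_request", config = standard_config("basic_ecg_10406")),
    apdu("assoc_response", result = "accepted"),
    apdu("assoc_response", result = "accepted_unknown_config"),
    apdu("assoc_response", result = "rejected"),
    apdu("config_report", config = standard_config("basic_ecg_10406")),
    apdu("config_response", config_id = 16385L, result = "accepted"),
    apdu("data_report_reliable", seq = 7L, timestamp_s = 12.5,
         observations = data.frame(handle = c(1L, 10L),
                                   mantissa = c(97L, 74L),
                                   exponent = c(0L, 0L))),
    apdu("data_report_reliable", seq = 8L, timestamp_s = 400,
         ecg_entry = list(hr_bpm = 48L, lead_off_status = 0L,
                          rr_last5_ms = c(1250L, 1250L, 1250L, 1250L, 1250L))),
    apdu("data_report_streaming", seq = 0L, samples = c(0.125, -1.5, 0.75)),
    apdu("ack", seq = 7L),
    apdu("release_request"),
    apdu("release_response"))
}

test_that("every constructible APDU survives an encode/decode round trip", {
  for (a in apdu_cases()) {
    expect_equal(decode_apdu(encode_apdu(a)), a, info = a$kind)
  }
})

test_that("a data report carries its SFLOAT-coded observation intact", {
  a <- apdu("data_report_reliable", seq = 1L, timestamp_s = 3,
            observations = data.frame(handle = 1L, mantissa = 97L,
                                      exponent = 0L))
  d <- decode_apdu(encode_apdu(a))
  expect_equal(d$observations$mantissa * 10^d$observations$exponent, 97)
  # streaming samples are bit-exact after the round trip
  x <- c(pi, -exp(1), 1 / 3)
  b <- decode_apdu(encode_apdu(apdu("data_report_streaming", seq = 2L,
                                    samples = x)))
  expect_identical(b$samples, x)
})

test_that("framing errors are reported with context", {
  expect_error(decode_apdu(raw(0)), "framing error")
  full <- encode_apdu(apdu("ack", seq = 1L))
  expect_error(decode_apdu(full[1:5]), "truncated")
  expect_error(decode_apdu(as.raw(c(0x12, 0x34, 0x00, 0x00))), "unknown kind")
  expect_error(apdu("abort"), "unknown APDU kind")
})

test_that("randomised APDU payloads round-trip (property check)", {
  set.seed(23)
  for (i in 1:50) {
    a <- apdu("data_report_streaming", seq = sample(0:65535, 1),
              samples = rnorm(sample(0:25, 1)))
    expect_equal(decode_apdu(encode_apdu(a)), a)
    b <- apdu("data_report_reliable", seq = sample(0:65535, 1),
              timestamp_s = runif(1, 0, 1e5),
              ecg_entry = list(hr_bpm = sample(30:220, 1),
                               lead_off_status = sample(0:1, 1),
                               rr_last5_ms = as.integer(sample(250:2000, 5,
                                                               replace = TRUE))))
    expect_equal(decode_apdu(encode_apdu(b)), b)
  }
})

test_that("device configurations match the agent object models", {
  spo2 <- standard_config("pulse_oximeter_10404")
  expect_true(spo2$standard)
  handles <- vapply(spo2$objects, `[[`, integer(1), "handle")
  expect_identical(handles, c(1L, 10L))  # saturation, pulse rate (hex A)
  expect_true(all(vapply(spo2$objects, `[[`, character(1),
                         "object_class") == "numeric"))

  ecg <- standard_config("basic_ecg_10406")
  expect_false(ecg$standard)
  expect_gte(ecg$config_id, 0x4000)  # extended configuration space
  classes <- vapply(ecg$objects, `[[`, character(1), "object_class")
  expect_setequal(classes, c("realtime_sample_array", "numeric", "status"))

  # both configs serialize and re-parse identically
  for (cfg in list(spo2, ecg)) {
    rt <- decode_apdu(encode_apdu(apdu("config_report", config = cfg)))$config
    expect_equal(rt, cfg)
  }
})
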