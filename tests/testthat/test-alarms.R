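# Alarm rules: warm-up discard, running mean, strict bounds, re-arming,
# ring buffer, event extraction.

feed_spo2 <- function(values, cfg = alarm_config()) {
  st <- spo2_alarm_state(cfg)
  warnings <- list()
  for (i in seq_along(values)) {
    step <- spo2_alarm_step(st, values[i], cfg, t_s = i)
    st <- step$state
    if (!is.null(step$warning))
      warnings[[length(warnings) + 1L]] <- step$warning
  }
  list(state = st, warnings = warnings)
}

test_that("warm-up values are discarded before any evaluation", {
  # four warm-up values of 50 then ten of 99: the 50s never count
  out <- feed_spo2(c(rep(50, 4), rep(99, 10)))
  expect_length(out$warnings, 0)
})

test_that("a low running mean fires at the first full window", {
  out <- feed_spo2(c(rep(98, 4), rep(94, 10)))
  expect_length(out$warnings, 1)
  expect_identical(out$warnings[[1]]$kind, "desaturation")
  expect_identical(out$warnings[[1]]$value, 94)
  expect_equal(out$warnings[[1]]$timestamp, 14)  # the 14th value
})

test_that("the desaturation bound is strict: a mean of exactly 95 is normal", {
  expect_length(feed_spo2(c(rep(98, 4), rep(95, 10)))$warnings, 0)
  expect_length(feed_spo2(c(rep(98, 4), rep(94.9, 10)))$warnings, 1)
})

test_that("no warning can fire before a full post-warm-up window exists", {
  # thirteen values, only nine post-warm-up: never evaluated
  expect_length(feed_spo2(c(rep(98, 4), rep(50, 9)))$warnings, 0)
})

test_that("desaturation warnings are edge-triggered and re-arm on recovery", {
  vals <- c(rep(98, 4), rep(90, 10),  # fires once
            rep(90, 5),               # stays in excursion: no second warning
            rep(100, 10),             # mean recovers: re-arms
            rep(90, 10))              # second excursion fires again
  out <- feed_spo2(vals)
  expect_length(out$warnings, 2)
})

test_that("out-of-range SpO2 values are rejected", {
  st <- spo2_alarm_state()
  expect_error(spo2_alarm_step(st, 104, alarm_config()), "\\[0, 100\\]")
  expect_error(spo2_alarm_step(st, -2, alarm_config()), "\\[0, 100\\]")
})

test_that("sweeping constant streams puts the warning boundary at 94/95", {
  fires <- vapply(85:100, function(level)
    length(feed_spo2(rep(level, 14))$warnings) > 0, logical(1))
  expect_identical(fires, 85:100 < 95)
})

test_that("heart-rate bounds are strict and symmetric around normal", {
  step1 <- function(hr) hr_alarm_step(hr_alarm_state(), hr, alarm_config())
  expect_identical(step1(59)$warning$kind, "bradycardia")
  expect_null(step1(60)$warning)
  expect_null(step1(100)$warning)
  expect_identical(step1(101)$warning$kind, "tachycardia")
  expect_error(step1(-5), "non-negative")
})

test_that("rate warnings are edge-triggered per excursion", {
  st <- hr_alarm_state()
  kinds <- character(0)
  for (hr in c(70, 55, 54, 53, 70, 55, 120, 121, 80)) {
    step <- hr_alarm_step(st, hr, alarm_config())
    st <- step$state
    if (!is.null(step$warning)) kinds <- c(kinds, step$warning$kind)
  }
  expect_identical(kinds, c("bradycardia", "bradycardia", "tachycardia"))
})

make_entry <- function(t, hr = 72L, samples = numeric(10)) {
  ecg_buffer_entry(hr, 0L, t, rep(800, 5), samples)
}

test_that("ring buffer ignores zero heart rates and evicts by timestamp", {
  cfg <- alarm_config()
  buf <- list()
  buf <- ring_store(buf, make_entry(1), cfg)
  expect_length(buf, 1)
  buf <- ring_store(buf, make_entry(2, hr = 0L), cfg)
  expect_length(buf, 1)
  # entries at t = 0..600 with a 300 s window: retained span is (300, 600]
  buf <- list()
  for (tt in seq(0, 600, by = 10)) buf <- ring_store(buf, make_entry(tt), cfg)
  ts <- vapply(buf, `[[`, numeric(1), "timestamp")
  expect_gt(min(ts), 300)
  expect_identical(max(ts), 600)
})

test_that("ring buffer never spans more than the pre-event window", {
  cfg <- alarm_config(pre_event_s = 50)
  buf <- list()
  for (tt in seq(0, 200, by = 1.3)) {
    buf <- ring_store(buf, make_entry(tt), cfg)
    ts <- vapply(buf, `[[`, numeric(1), "timestamp")
    expect_lte(max(ts) - min(ts), 50)
  }
})

test_that("event records span five minutes back, clamped to session start", {
  cfg <- alarm_config()
  buf <- list()
  for (tt in seq(0, 450, by = 5)) buf <- ring_store(buf, make_entry(tt), cfg)
  w <- list(kind = "bradycardia", timestamp = 400, value = 50L)
  rec <- extract_event(buf, w, cfg)
  expect_identical(rec$start_s, 100)
  ts <- vapply(rec$entries, `[[`, numeric(1), "timestamp")
  expect_gte(min(ts), 100)
  expect_lte(max(ts), 400)
  # early event: record starts at the session start
  w2 <- list(kind = "bradycardia", timestamp = 120, value = 50L)
  expect_identical(extract_event(buf, w2, cfg)$start_s, 0)
  # empty buffer: warning-only record
  expect_length(extract_event(list(), w, cfg)$entries, 0)
})

test_that("post-event appends complete the ten-minute record", {
  cfg <- alarm_config()
  buf <- list()
  for (tt in seq(0, 400, by = 5)) buf <- ring_store(buf, make_entry(tt), cfg)
  w <- list(kind = "tachycardia", timestamp = 400, value = 130L)
  rec <- extract_event(buf, w, cfg)
  expect_identical(rec$end_s, 700)
  for (tt in seq(405, 800, by = 5))
    rec <- event_record_append(rec, make_entry(tt), cfg)
  ts <- vapply(rec$entries, `[[`, numeric(1), "timestamp")
  expect_equal(max(ts), 700)           # capped at t_event + post_event_s
  expect_equal(rec$end_s - rec$start_s, 600)  # full ten-minute span
  expect_gte(min(ts), rec$start_s)
  expect_true(all(diff(ts) >= 0))
})
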