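# Monitoring scenarios: a stream plus the warnings the alarm engine must raise.

#' Build a named monitoring scenario
#'
#' Returns a synthetic stream together with the warnings the alarm engine is
#' expected to raise on it (kind plus a time window), so that end-to-end
#' sessions can be checked against a construction-time answer. SpO2-centred
#' scenarios (`rest`, `desaturation_event`) produce PPG streams handled by
#' the pulse-oximeter agent; rate-centred scenarios (`exercise`,
#' `bradycardia_event`, `tachycardia_event`) produce ECG streams handled by
#' the ECG agent.
#'
#' The event scenarios embed a generous excursion: `desaturation_event` dips
#' to 88% saturation for 30 s (about 37 beats at 75 bpm), well past the
#' 10-value running mean; the rate events hold 45 bpm / 130 bpm for 30 s.
#' Expected warning windows account for measurement cadence (SpO2 every
#' three beats, heart rate from a rolling mean of up to five R-R intervals).
#'
#' @param name one of `"rest"`, `"exercise"`, `"desaturation_event"`,
#'   `"bradycardia_event"`, `"tachycardia_event"`.
#' @param seed integer seed forwarded to the generator.
#' @return a list of class `scenario`: `name`, `seed`, `stream` (a
#'   `ppg_stream` or `ecg_stream`), `kind` (`"ppg"` or `"ecg"`), and
#'   `expected_warnings`, a data frame with columns `kind`, `t_min`, `t_max`
#'   (empty when no warning is expected).
#' @export
make_scenario <- function(name, seed = 1L) {
  seed <- as.integer(seed)
  no_warn <- data.frame(kind = character(), t_min = numeric(),
                        t_max = numeric(), stringsAsFactors = FALSE)
  sc <- switch(
    name,
    rest = list(
      stream = generate_ppg(ppg_spec(duration_s = 60, pulse_bpm = 72,
                                     target_spo2_pct = 98,
                                     noise_sd = 0.002, seed = seed)),
      kind = "ppg", expected_warnings = no_warn),
    desaturation_event = list(
      stream = generate_ppg(ppg_spec(
        duration_s = 70, pulse_bpm = 75,
        spo2_schedule = rbind(c(0, 97), c(25, 88), c(55, 97)),
        noise_sd = 0.002, seed = seed)),
      kind = "ppg",
      expected_warnings = data.frame(kind = "desaturation",
                                     t_min = 29, t_max = 43,
                                     stringsAsFactors = FALSE)),
    exercise = list(
      stream = generate_ecg(ecg_spec(
        duration_s = 60, hr_bpm = rbind(c(0, 78), c(30, 95)),
        mains_amp = 0.05, wander_amp = 0.1, noise_sd = 0.01, seed = seed)),
      kind = "ecg", expected_warnings = no_warn),
    bradycardia_event = list(
      stream = generate_ecg(ecg_spec(
        duration_s = 70, hr_bpm = rbind(c(0, 72), c(20, 45), c(50, 72)),
        mains_amp = 0.05, wander_amp = 0.1, noise_sd = 0.01, seed = seed)),
      kind = "ecg",
      expected_warnings = data.frame(kind = "bradycardia",
                                     t_min = 21, t_max = 30,
                                     stringsAsFactors = FALSE)),
    tachycardia_event = list(
      stream = generate_ecg(ecg_spec(
        duration_s = 70, hr_bpm = rbind(c(0, 80), c(20, 130), c(50, 80)),
        mains_amp = 0.05, wander_amp = 0.1, noise_sd = 0.01, seed = seed)),
      kind = "ecg",
      expected_warnings = data.frame(kind = "tachycardia",
                                     t_min = 20, t_max = 28,
                                     stringsAsFactors = FALSE)),
    stopf("unknown scenario name: %s", name)
  )
  structure(c(list(name = name, seed = seed), sc), class = "scenario")
}

#' Names of the available scenarios
#' @return character vector.
#' @export
scenario_names <- function() {
  c("rest", "exercise", "desaturation_event",
    "bradycardia_event", "tachycardia_event")
}
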