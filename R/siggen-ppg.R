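# Synthetic two-channel (red / infrared) photoplethysmogram generation.

#' Specify a synthetic PPG stream
#'
#' Describes a two-channel (red + infrared) photoplethysmogram with a known
#' oxygen-saturation ground truth. Each optical channel is modelled as a DC
#' absorbance level plus a pulsatile AC component scaled so that the
#' ratio-of-ratios computed downstream maps back to `target_spo2_pct` through
#' the default calibration curve (see [calibrate()]).
#'
#' @param duration_s stream length, seconds.
#' @param fs_hz sampling rate, samples/second. Default 1000 (a 1 ms read
#'   cadence, typical of pulse-oximeter front ends).
#' @param pulse_bpm pulse rate, beats/minute.
#' @param target_spo2_pct ground-truth oxygen saturation, percent, in
#'   \[70, 100\]. May also be given as `spo2_schedule`.
#' @param dc_red,dc_ir baseline (DC) absorbance of each channel, arbitrary
#'   units, strictly positive.
#' @param perfusion_ir pulsatile AC/DC fraction of the infrared channel,
#'   dimensionless, in (0, 0.2\]. A value of 0 is accepted as a degenerate
#'   no-pulse override.
#' @param noise_sd additive white Gaussian noise, absorbance units.
#' @param seed integer seed; identical specs with identical seeds generate
#'   bit-identical streams.
#' @param spo2_schedule optional piecewise-constant saturation schedule, a
#'   two-column matrix of (t_start_s, spo2_pct) rows; overrides
#'   `target_spo2_pct` when supplied.
#' @return an object of class `ppg_spec`.
#' @export
ppg_spec <- function(duration_s, fs_hz = 1000, pulse_bpm = 74,
                     target_spo2_pct = 97, dc_red = 1.5, dc_ir = 2.0,
                     perfusion_ir = 0.05, noise_sd = 0, seed = 1L,
                     spo2_schedule = NULL) {
  if (duration_s <= 0) stopf("duration_s must be positive")
  if (fs_hz <= 0) stopf("fs_hz must be positive")
  if (pulse_bpm <= 0) stopf("pulse_bpm must be positive")
  if (dc_red <= 0 || dc_ir <= 0) stopf("DC levels must be positive")
  if (perfusion_ir < 0 || perfusion_ir > 0.2)
    stopf("perfusion_ir must lie in [0, 0.2]")
  if (is.null(spo2_schedule)) {
    if (target_spo2_pct < 70 || target_spo2_pct > 100)
      stopf("target_spo2_pct must lie in [70, 100]")
    spo2_schedule <- matrix(c(0, target_spo2_pct), nrow = 1)
  } else {
    spo2_schedule <- as_schedule(spo2_schedule, duration_s, "spo2_schedule")
    if (any(spo2_schedule[, 2] < 70) || any(spo2_schedule[, 2] > 100))
      stopf("scheduled spo2 values must lie in [70, 100]")
  }
  # pulse fundamental plus a few harmonics must stay below Nyquist
  if (fs_hz <= 2 * (pulse_bpm / 60) * 20)
    stopf("fs_hz too low for the requested pulse rate")
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 pulse_bpm = pulse_bpm, spo2_schedule = spo2_schedule,
                 dc_red = dc_red, dc_ir = dc_ir,
                 perfusion_ir = perfusion_ir, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ppg_spec")
}

# Zero-mean pulse waveform over beat phase u in [0,1): a raised-cosine
# systolic peak (apex at u = 0.3) plus a smaller diastolic bump at u = 0.68.
# The analytic mean (0.12 + 0.35 * 0.10) is subtracted so that window means
# estimate the DC level without bias.
ppg_pulse_wave <- function(u) {
  bump <- function(u, centre, half_width) {
    d <- abs(u - centre)
    ifelse(d <= half_width, 0.5 * (1 + cos(pi * d / half_width)), 0)
  }
  bump(u, 0.30, 0.12) + 0.35 * bump(u, 0.68, 0.10) - (0.12 + 0.35 * 0.10)
}

#' Generate a synthetic PPG stream
#'
#' Builds the red and infrared absorbance channels from a [ppg_spec()]. The
#' infrared AC amplitude is `perfusion_ir * dc_ir`; the red AC amplitude is
#' set to `R * perfusion_ir * dc_red` where `R` is the ratio-of-ratios that
#' the default calibration maps to the requested saturation, so a noise-free
#' stream round-trips through the SpO2 pipeline exactly. Ground truth
#' (saturation, pulse rate, beat times at the systolic apex) is captured
#' before noise is added.
#'
#' @param spec a [ppg_spec()].
#' @return an object of class `ppg_stream` with elements `red`, `ir`
#'   (numeric vectors), `fs_hz`, and `truth` (list with `spo2_pct`,
#'   `pulse_bpm`, `beat_times_s`).
#' @export
generate_ppg <- function(spec) {
  stopifnot(inherits(spec, "ppg_spec"))
  n <- round(spec$duration_s * spec$fs_hz)
  t <- (seq_len(n) - 1) / spec$fs_hz
  period <- 60 / spec$pulse_bpm
  u <- (t %% period) / period
  wave <- ppg_pulse_wave(u)

  spo2_t <- schedule_at(spec$spo2_schedule, t)
  ratio_t <- ratio_for_spo2(spo2_t)
  a_ir <- spec$perfusion_ir * spec$dc_ir
  a_red_t <- ratio_t * spec$perfusion_ir * spec$dc_red

  # truth: systolic apex times (u = 0.3), strictly increasing
  k <- 0:floor(spec$duration_s / period)
  beat_times <- (k + 0.3) * period
  beat_times <- beat_times[beat_times < spec$duration_s]

  red <- spec$dc_red + a_red_t * wave
  ir <- spec$dc_ir + a_ir * wave
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, stats::rnorm(2 * n, sd = spec$noise_sd))
    red <- red + noise[seq_len(n)]
    ir <- ir + noise[n + seq_len(n)]
  }

  truth_spo2 <- if (nrow(spec$spo2_schedule) == 1) spec$spo2_schedule[1, 2]
                else spec$spo2_schedule
  structure(list(red = red, ir = ir, fs_hz = spec$fs_hz,
                 truth = list(spo2_pct = truth_spo2,
                              pulse_bpm = spec$pulse_bpm,
                              beat_times_s = beat_times),
                 spec = spec),
            class = "ppg_stream")
}
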