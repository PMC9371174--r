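# Ratio-of-ratios SpO2 estimation with a replaceable calibration LUT.

#' Default SpO2 calibration look-up table
#'
#' A 256-entry table sampling the standard first-order empirical pulse-ox
#' curve `SpO2 = 110 - 25 * R` (R the DC-normalised ratio-of-ratios),
#' clipped to \[0, 100\], over R in \[0, 2.55\]. The table can be replaced by
#' any monotonically non-increasing calibration loaded with
#' [read_spo2_lut()].
#'
#' @return a data frame with columns `ratio` and `spo2`.
#' @export
spo2_lut <- function() {
  ratio <- seq(0, 2.55, length.out = 256)
  data.frame(ratio = ratio, spo2 = pmin(100, pmax(0, 110 - 25 * ratio)))
}

#' Map a ratio-of-ratios to an SpO2 percentage
#'
#' Linear interpolation into the calibration table; ratios beyond the table
#' are clamped to its end values. The default table is the curve
#' `SpO2 = 110 - 25 * R`.
#'
#' @param ratio non-negative ratio-of-ratios value(s).
#' @param lut calibration table, as from [spo2_lut()] or [read_spo2_lut()].
#' @return SpO2 percentage(s) in \[0, 100\].
#' @export
calibrate <- function(ratio, lut = spo2_lut()) {
  if (any(ratio < 0)) stopf("ratio must be non-negative")
  stats::approx(lut$ratio, lut$spo2, xout = ratio, rule = 2)$y
}

# inverse of the calibration over its strictly decreasing region; used by
# the generator to choose the red AC amplitude for a target saturation
ratio_for_spo2 <- function(spo2_pct, lut = spo2_lut()) {
  dec <- which(lut$spo2 < 100 & lut$spo2 > 0)
  # include the clip boundaries so a target of exactly 100 resolves to the
  # largest ratio still mapping to 100
  idx <- unique(c(max(min(dec) - 1L, 1L), dec, min(max(dec) + 1L, nrow(lut))))
  stats::approx(rev(lut$spo2[idx]), rev(lut$ratio[idx]), xout = spo2_pct,
                rule = 2, ties = "ordered")$y
}

#' Compute an SpO2 measurement from beat-windowed AC/DC values
#'
#' The R-value is the DC-normalised ratio-of-ratios
#' `R = (RMS(red_ac)/red_dc) / (RMS(ir_ac)/ir_dc)` (set `raw_ratio = TRUE`
#' for the plain RMS ratio without DC normalisation), mapped through the
#' calibration table. A measurement is emitted only when at least three
#' beats have elapsed since the previous emission; an infrared AC level
#' below the pulse floor yields a no-pulse marker instead of a value.
#'
#' @param red_ac,ir_ac AC (filtered) samples over the window covering the
#'   last three detected beats.
#' @param red_dc,ir_dc DC levels over the same window.
#' @param beats_elapsed beats since the last emission.
#' @param t_s timestamp, seconds from session start.
#' @param pulse_bpm optional pulse rate to attach.
#' @param lut calibration table.
#' @param raw_ratio if `TRUE`, use `RMS(red)/RMS(ir)` without DC
#'   normalisation (literal-fidelity mode).
#' @param pulse_floor minimum `RMS(ir_ac)/ir_dc` treated as a pulse.
#' @return `NULL` if fewer than three beats have elapsed; otherwise an
#'   object of class `spo2_measurement` with `spo2_pct`, `pulse_bpm`,
#'   `timestamp`, `ratio`, `no_pulse`.
#' @export
compute_spo2 <- function(red_ac, ir_ac, red_dc, ir_dc, beats_elapsed = 3,
                         t_s = NA_real_, pulse_bpm = NA_real_,
                         lut = spo2_lut(), raw_ratio = FALSE,
                         pulse_floor = 1e-4) {
  if (beats_elapsed < 3) return(NULL)
  if (ir_dc <= 0 || red_dc <= 0) stopf("DC levels must be positive")
  if (rms(ir_ac) / ir_dc < pulse_floor) {
    return(structure(list(spo2_pct = NA_real_, pulse_bpm = NA_real_,
                          timestamp = t_s, ratio = NA_real_,
                          no_pulse = TRUE),
                     class = "spo2_measurement"))
  }
  ratio <- if (raw_ratio) rms(red_ac) / rms(ir_ac)
           else (rms(red_ac) / red_dc) / (rms(ir_ac) / ir_dc)
  structure(list(spo2_pct = min(100, max(0, calibrate(ratio, lut))),
                 pulse_bpm = pulse_bpm, timestamp = t_s, ratio = ratio,
                 no_pulse = FALSE),
            class = "spo2_measurement")
}

#' Peak-to-peak scale of a plethysmographic window
#'
#' `RMS * 2 * sqrt(2)`: the peak-to-peak amplitude of the sinusoid with the
#' window's RMS power, used to scale display samples of the pleth waveform.
#'
#' @param window numeric samples (DC-removed).
#' @return non-negative scalar.
#' @export
square_root_scale <- function(window) {
  if (length(window) == 0) return(0)
  rms(window) * 2 * sqrt(2)
}

#' Run the full SpO2 pipeline on a PPG stream
#'
#' DC-blocks and FIR low-pass filters both optical channels, detects beats
#' on the filtered infrared channel with an adaptive peak picker, and emits
#' one measurement every three beats: the R-value over the trailing
#' three-beat window, the calibrated saturation, and the pulse rate from
#' the same three beats.
#'
#' @param stream a `ppg_stream`.
#' @param lut calibration table.
#' @param raw_ratio see [compute_spo2()].
#' @return a data frame with columns `t_s`, `spo2_pct`, `pulse_bpm`,
#'   `ratio` (zero rows, with attribute `no_pulse = TRUE`, when no pulse is
#'   found).
#' @export
process_ppg <- function(stream, lut = spo2_lut(), raw_ratio = FALSE) {
  stopifnot(inherits(stream, "ppg_stream"))
  fs <- stream$fs_hz
  coef <- design_fir_lowpass(filter_spec("fir_lowpass", fs_hz = fs))
  red_f <- fir_filter(dc_block(stream$red), coef)
  ir_f <- fir_filter(dc_block(stream$ir), coef)

  beats <- detect_ppg_beats(ir_f, fs)
  empty <- data.frame(t_s = numeric(0), spo2_pct = numeric(0),
                      pulse_bpm = numeric(0), ratio = numeric(0))
  if (length(beats) < 4) {
    attr(empty, "no_pulse") <- TRUE
    return(empty)
  }

  rows <- list()
  for (k in seq(4, length(beats), by = 3)) {
    i0 <- beats[k - 3]; i1 <- beats[k]
    red_w <- red_f[i0:i1]; ir_w <- ir_f[i0:i1]
    red_dc <- mean(stream$red[i0:i1]); ir_dc <- mean(stream$ir[i0:i1])
    t_s <- (i1 - 1) / fs
    pulse <- 60 * 3 / ((i1 - i0) / fs)
    m <- compute_spo2(red_w, ir_w, red_dc, ir_dc, beats_elapsed = 3,
                      t_s = t_s, pulse_bpm = pulse, lut = lut,
                      raw_ratio = raw_ratio)
    if (!m$no_pulse)
      rows[[length(rows) + 1L]] <-
        data.frame(t_s = t_s, spo2_pct = m$spo2_pct, pulse_bpm = pulse,
                   ratio = m$ratio)
  }
  if (length(rows) == 0) {
    attr(empty, "no_pulse") <- TRUE
    return(empty)
  }
  do.call(rbind, rows)
}

# Adaptive beat picker for the filtered infrared pleth: local maxima above
# half a decaying running-peak estimate, 250 ms refractory. Detection starts
# after a 2 s settling window so the DC-blocker step transient (time
# constant ~0.2 s at the default alpha) cannot seed the peak estimate.
detect_ppg_beats <- function(ir_f, fs_hz, refractory_s = 0.25) {
  n <- length(ir_f)
  refr <- round(refractory_s * fs_hz)
  settle <- round(2 * fs_hz)
  if (n <= settle + refr) return(integer(0))
  peak_est <- max(ir_f[settle:n])
  if (peak_est <= 1e-12) return(integer(0))
  peaks <- integer(0)
  last <- -Inf
  for (i in (settle + 1L):(n - 1)) {
    if (ir_f[i] > ir_f[i - 1] && ir_f[i] >= ir_f[i + 1] &&
        ir_f[i] > 0.5 * peak_est && (i - last) > refr) {
      peaks <- c(peaks, i)
      last <- i
      peak_est <- max(ir_f[i], 0.8 * peak_est)
    }
  }
  peaks
}
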