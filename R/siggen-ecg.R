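# Synthetic 8-lead ECG generation with ground-truth R-peak times.

#' Specify a synthetic ECG stream
#'
#' Describes an 8-lead acquired ECG (I, II, V1--V6) built from a
#' sum-of-Gaussians PQRST template repeated at a scheduled heart rate, with
#' optional baseline wander, 50/60 Hz mains interference, additive noise,
#' and a lead-off schedule.
#'
#' @param duration_s stream length, seconds.
#' @param fs_hz sampling rate, samples/second; default 500 (a 2 ms read
#'   interrupt cadence).
#' @param hr_bpm heart rate in beats/minute: either a scalar or a
#'   piecewise-constant schedule given as a two-column matrix of
#'   (t_start_s, hr_bpm) rows with non-decreasing times in \[0, duration_s\].
#' @param mains_hz mains interference frequency, 50 or 60.
#' @param mains_amp,wander_amp,noise_sd amplitudes of the mains sinusoid,
#'   0.3 Hz baseline wander, and white noise, millivolts.
#' @param lead_off optional list of `c(start_s, end_s)` intervals during
#'   which the lead-off status flag is raised.
#' @param seed integer seed (determinism contract as for [ppg_spec()]).
#' @return an object of class `ecg_spec`.
#' @export
ecg_spec <- function(duration_s, fs_hz = 500, hr_bpm = 72, mains_hz = 50,
                     mains_amp = 0, wander_amp = 0, noise_sd = 0,
                     lead_off = NULL, seed = 1L) {
  if (duration_s <= 0) stopf("duration_s must be positive")
  if (fs_hz <= 0) stopf("fs_hz must be positive")
  hr_schedule <- as_schedule(hr_bpm, duration_s, "hr schedule")
  if (any(hr_schedule[, 2] <= 0)) stopf("hr_bpm must be positive")
  if (!mains_hz %in% c(50, 60)) stopf("mains_hz must be 50 or 60")
  if (!is.null(lead_off)) {
    for (iv in lead_off)
      if (length(iv) != 2 || iv[1] >= iv[2])
        stopf("lead_off intervals must be c(start, end) with start < end")
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 hr_schedule = hr_schedule, mains_hz = mains_hz,
                 mains_amp = mains_amp, wander_amp = wander_amp,
                 noise_sd = noise_sd, lead_off = lead_off,
                 seed = as.integer(seed)),
            class = "ecg_spec")
}

# PQRST template: five Gaussian components with offsets and widths in
# seconds (values at a 1 s R-R interval), R apex at offset 0 with amplitude
# 1 mV on lead II. The QRS complex (Q, R, S) keeps a fixed absolute
# duration at all rates, as in real ECG; the P and T components scale with
# sqrt(RR) (Bazett-style QT shortening). The P/Q/S/T components are far
# enough from the apex that the summed maximum stays at offset 0 to well
# under one sample at 500 sps.
ecg_template_components <- function() {
  data.frame(offset_s = c(-0.194, -0.041, 0.000, 0.041, 0.278),
             amp      = c( 0.12, -0.12, 1.00, -0.17, 0.30),
             width_s  = c( 0.035, 0.011, 0.0095, 0.011, 0.056),
             rate_scaled = c(TRUE, FALSE, FALSE, FALSE, TRUE),
             row.names = c("P", "Q", "R", "S", "T"))
}

# relative amplitudes of the acquired leads w.r.t. lead II
ecg_lead_scales <- function() {
  c(I = 0.5, II = 1, V1 = -0.3, V2 = 0.2, V3 = 0.5,
    V4 = 0.9, V5 = 1.1, V6 = 0.8)
}

#' Generate a synthetic ECG stream
#'
#' Lead II is built by placing the PQRST template at beat times that follow
#' the heart-rate schedule; beat (R apex) times are snapped to the sample
#' grid and recorded as ground truth before wander, mains interference, and
#' noise are added. The remaining acquired leads are scaled copies of
#' lead II, which keeps the Einthoven identity I + III = II exact once
#' lead III is derived downstream.
#'
#' @param spec an [ecg_spec()].
#' @return an object of class `ecg_stream` with elements `leads8` (an
#'   8 x n matrix, rows I, II, V1--V6, millivolts), `lead_off_status`
#'   (integer per-sample code, 0 = attached), `fs_hz`, and `truth` (list
#'   with `r_peak_times_s` and `hr_schedule`).
#' @export
generate_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_spec"))
  fs <- spec$fs_hz
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  # beat placement: first R apex after a 0.4 s lead-in, then advance by the
  # scheduled R-R interval; apex times snapped to the sample grid
  r_times <- numeric(0)
  r_cont <- 0.4
  while (r_cont < spec$duration_s) {
    r_times <- c(r_times, round(r_cont * fs) / fs)
    r_cont <- r_cont + 60 / schedule_at(spec$hr_schedule, r_cont)
  }

  comp <- ecg_template_components()
  lead2 <- numeric(n)
  for (k in seq_along(r_times)) {
    rk <- r_times[k]
    period <- 60 / schedule_at(spec$hr_schedule, rk)
    i0 <- max(1L, floor((rk - 0.55 * period) * fs) + 1L)
    i1 <- min(n, ceiling((rk + 0.55 * period) * fs) + 1L)
    if (i0 > i1) next
    dt <- t[i0:i1] - rk
    seg <- numeric(i1 - i0 + 1L)
    inside <- abs(dt) <= 0.55 * period
    bazett <- sqrt(period)
    for (j in seq_len(nrow(comp))) {
      sc <- if (comp$rate_scaled[j]) bazett else 1
      seg[inside] <- seg[inside] +
        comp$amp[j] * exp(-(dt[inside] - comp$offset_s[j] * sc)^2 /
                            (2 * (comp$width_s[j] * sc)^2))
    }
    lead2[i0:i1] <- lead2[i0:i1] + seg
  }

  scales <- ecg_lead_scales()
  leads8 <- outer(scales, lead2)
  rownames(leads8) <- names(scales)

  # artefacts are added after truth capture
  if (spec$mains_amp > 0 || spec$wander_amp > 0 || spec$noise_sd > 0) {
    artefact <- with_seed(spec$seed, {
      phases <- stats::runif(16, 0, 2 * pi)
      nz <- if (spec$noise_sd > 0)
        matrix(stats::rnorm(8 * n, sd = spec$noise_sd), nrow = 8)
      else matrix(0, nrow = 8, ncol = n)
      list(phases = phases, noise = nz)
    })
    for (l in 1:8) {
      if (spec$mains_amp > 0)
        leads8[l, ] <- leads8[l, ] +
          spec$mains_amp * sin(2 * pi * spec$mains_hz * t + artefact$phases[l])
      if (spec$wander_amp > 0)
        leads8[l, ] <- leads8[l, ] +
          spec$wander_amp * sin(2 * pi * 0.3 * t + artefact$phases[8 + l])
    }
    leads8 <- leads8 + artefact$noise
  }

  lead_off_status <- integer(n)
  for (iv in spec$lead_off)
    lead_off_status[t >= iv[1] & t < iv[2]] <- 1L

  structure(list(leads8 = leads8, lead_off_status = lead_off_status,
                 fs_hz = fs,
                 truth = list(r_peak_times_s = r_times,
                              hr_schedule = spec$hr_schedule),
                 spec = spec),
            class = "ecg_stream")
}
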