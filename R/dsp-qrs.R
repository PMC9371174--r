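# Variable-threshold QRS detection and heart-rate computation.

#' QRS detector configuration
#'
#' Parameters of the variable-threshold detector: the detection threshold is
#' `threshold_fraction` times a running peak-amplitude estimate that decays
#' by `peak_decay_per_beat` at each detected beat, with a hard refractory
#' period and a QRS-emphasising band-pass stage.
#'
#' @param threshold_fraction fraction of the running peak estimate, (0, 1).
#' @param peak_decay_per_beat per-beat decay of the peak estimate, (0, 1\].
#' @param refractory_ms minimum spacing between detections, milliseconds.
#' @param search_band_hz two-element band (Hz) of the QRS band-pass stage.
#' @return an object of class `qrs_config`.
#' @export
qrs_config <- function(threshold_fraction = 0.5, peak_decay_per_beat = 0.8,
                       refractory_ms = 200, search_band_hz = c(5, 15)) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stopf("threshold_fraction must lie in (0, 1)")
  if (refractory_ms <= 0) stopf("refractory_ms must be positive")
  if (length(search_band_hz) != 2 || search_band_hz[1] >= search_band_hz[2])
    stopf("search_band_hz must be an increasing pair")
  structure(list(threshold_fraction = threshold_fraction,
                 peak_decay_per_beat = peak_decay_per_beat,
                 refractory_ms = refractory_ms,
                 search_band_hz = search_band_hz),
            class = "qrs_config")
}

#' Detect R-peaks on lead II
#'
#' A variable-threshold chain in the Pan--Tompkins style: causal band-pass
#' (5--15 Hz Butterworth), derivative, squaring, 150 ms moving-window
#' integration, then an adaptive threshold at `threshold_fraction` times a
#' running peak estimate with per-beat decay and a refractory period.
#' Detected integration peaks are mapped back to the R apex by an argmax
#' over the preceding 250 ms of the input lead.
#'
#' @param lead_ii numeric signal, assumed DC-blocked and notch-filtered.
#' @param fs_hz sampling rate, Hz.
#' @param cfg a [qrs_config()].
#' @return an `rr_series`: list with `peak_indices` (1-based sample indices,
#'   strictly increasing), `intervals_ms`, and `fs_hz`.
#' @export
detect_qrs <- function(lead_ii, fs_hz, cfg = qrs_config()) {
  refr <- round(cfg$refractory_ms / 1000 * fs_hz)
  empty <- structure(list(peak_indices = integer(0),
                          intervals_ms = numeric(0), fs_hz = fs_hz),
                     class = "rr_series")
  n <- length(lead_ii)
  if (n <= refr) return(empty)

  bp <- signal::butter(3, cfg$search_band_hz / (fs_hz / 2), type = "pass")
  x <- as.numeric(signal::filter(bp$b, bp$a, lead_ii))
  d <- c(0, diff(x))
  sq <- d^2
  win <- max(1L, round(0.150 * fs_hz))
  integ <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 1))
  integ[is.na(integ)] <- 0

  # running peak estimate initialised from the first 1.5 s (>= 1 beat at
  # any plausible rate)
  init_n <- min(n, max(win + 1L, round(1.5 * fs_hz)))
  peak_est <- max(integ[seq_len(init_n)])
  if (peak_est <= 0) return(empty)

  peaks <- integer(0)
  last <- -Inf
  i <- 2L
  while (i < n) {
    if (integ[i] > integ[i - 1] && integ[i] >= integ[i + 1] &&
        integ[i] > cfg$threshold_fraction * peak_est &&
        (i - last) > refr) {
      # map the integration peak back to the R apex on the input lead
      lo <- max(1L, i - round(0.250 * fs_hz))
      r_idx <- lo - 1L + which.max(lead_ii[lo:i])
      if (length(peaks) == 0 || r_idx - peaks[length(peaks)] > refr) {
        peaks <- c(peaks, r_idx)
        last <- i
        peak_est <- max(integ[i], cfg$peak_decay_per_beat * peak_est)
      }
    }
    i <- i + 1L
  }
  structure(list(peak_indices = peaks,
                 intervals_ms = diff(peaks) * 1000 / fs_hz,
                 fs_hz = fs_hz),
            class = "rr_series")
}

#' Heart rate from an R-R series
#'
#' No value is produced until five R-peaks have been observed; from then on
#' the rate is `60000 / mean(last up-to-5 intervals in ms)`, rounded to the
#' nearest integer bpm. The timestamp is the time of the most recent peak.
#'
#' @param rr an `rr_series` from [detect_qrs()].
#' @return `NULL`, or a list with `hr_bpm` (integer) and `t_s`.
#' @export
compute_hr <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$peak_indices) < 5) return(NULL)
  iv <- utils::tail(rr$intervals_ms, 5)
  list(hr_bpm = as.integer(round(60000 / mean(iv))),
       t_s = (rr$peak_indices[length(rr$peak_indices)] - 1) / rr$fs_hz)
}

# HR time series: one value per peak from the fifth onwards, each from the
# trailing <= 5 intervals; rr_last5 is padded by repeating the oldest
# available interval until five exist.
hr_series <- function(rr) {
  np <- length(rr$peak_indices)
  if (np < 5) {
    return(data.frame(t_s = numeric(0), hr_bpm = integer(0)))
  }
  out <- vector("list", np - 4L)
  for (k in 5:np) {
    iv <- rr$intervals_ms[max(1, k - 5):(k - 1)]
    iv5 <- if (length(iv) >= 5) utils::tail(iv, 5)
           else c(rep(iv[1], 5 - length(iv)), iv)
    out[[k - 4L]] <- list(t_s = (rr$peak_indices[k] - 1) / rr$fs_hz,
                          hr_bpm = as.integer(round(60000 / mean(iv))),
                          rr_last5_ms = iv5)
  }
  out
}
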