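# Front-end filters: DC blocker, Hamming-windowed low-pass FIR, mains notch.

#' Specify a front-end filter
#'
#' @param kind `"fir_lowpass"`, `"iir_dc_block"`, or `"notch"`.
#' @param order FIR order (taps - 1); default 51.
#' @param cutoff_hz low-pass cutoff, Hz; default 10 (plethysmogram band).
#' @param notch_hz mains frequency, 50 or 60.
#' @param window FIR window; only `"hamming"` is provided.
#' @param fs_hz sampling rate the filter is designed for.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("fir_lowpass", "iir_dc_block", "notch"),
                        order = 51, cutoff_hz = 10, notch_hz = 50,
                        window = "hamming", fs_hz = 1000) {
  kind <- match.arg(kind)
  if (order < 1) stopf("order must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2)
    stopf("cutoff_hz must lie in (0, fs_hz/2)")
  if (!notch_hz %in% c(50, 60)) stopf("notch_hz must be 50 or 60")
  if (window != "hamming") stopf("only the Hamming window is supported")
  structure(list(kind = kind, order = order, cutoff_hz = cutoff_hz,
                 notch_hz = notch_hz, window = window, fs_hz = fs_hz),
            class = "filter_spec")
}

#' First-order IIR DC blocker
#'
#' `y[n] = alpha * y[n-1] + x[n] - x[n-1]`: removes the DC component with a
#' sub-0.5 Hz corner at the default `alpha`. Causal; a constant input decays
#' to zero geometrically at rate `alpha`.
#'
#' @param x numeric signal.
#' @param alpha pole location, in (0, 1); default 0.995.
#' @return filtered signal, same length as `x`.
#' @export
dc_block <- function(x, alpha = 0.995) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (length(x) == 0) return(numeric(0))
  as.numeric(signal::filter(c(1, -1), c(1, -alpha), x))
}

#' Design the Hamming-windowed low-pass FIR
#'
#' Returns `order + 1` symmetric taps normalised to unity DC gain
#' (coefficients sum to 1), giving a linear-phase low-pass with group delay
#' `order / 2` samples.
#'
#' @param spec a [filter_spec()] of kind `"fir_lowpass"` (order, cutoff, fs),
#'   or missing to use the defaults (order 51, 10 Hz at 1000 sps).
#' @return numeric coefficient vector of length `order + 1`.
#' @export
design_fir_lowpass <- function(spec = filter_spec("fir_lowpass")) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff_hz >= spec$fs_hz / 2) stopf("cutoff at or above Nyquist")
  h <- signal::fir1(spec$order, spec$cutoff_hz / (spec$fs_hz / 2),
                    type = "low", window = signal::hamming(spec$order + 1))
  as.numeric(h) / sum(h)
}

#' Apply an FIR filter causally
#'
#' @param x numeric signal.
#' @param coef FIR taps, e.g. from [design_fir_lowpass()].
#' @return filtered signal (delayed by `length(coef)/2` samples).
#' @export
fir_filter <- function(x, coef) {
  if (length(x) == 0) return(numeric(0))
  as.numeric(signal::filter(coef, 1, x))
}

# biquad notch coefficients: zeros on the unit circle at +/- notch_hz, poles
# at radius `pole_radius` just inside; gain normalised to 1 at DC.
notch_coefficients <- function(notch_hz, fs_hz, pole_radius = 0.975) {
  if (notch_hz >= fs_hz / 2) stopf("notch_hz must be below Nyquist")
  w0 <- 2 * pi * notch_hz / fs_hz
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * pole_radius * cos(w0), pole_radius^2)
  list(b = b * sum(a) / sum(b), a = a)
}

#' Mains notch filter
#'
#' Second-order IIR notch at 50 or 60 Hz. The zeros sit exactly on the unit
#' circle, so a steady mains sinusoid is nulled; the default pole radius
#' 0.975 keeps the notch narrow enough that the ECG passband (<= 40 Hz at
#' 500 sps) is attenuated by well under 1 dB.
#'
#' @param x numeric signal.
#' @param notch_hz 50 or 60.
#' @param fs_hz sampling rate, Hz.
#' @param pole_radius notch-width control, in (0, 1).
#' @return filtered signal.
#' @export
notch_filter <- function(x, notch_hz, fs_hz, pole_radius = 0.975) {
  if (length(x) == 0) return(numeric(0))
  nc <- notch_coefficients(notch_hz, fs_hz, pole_radius)
  as.numeric(signal::filter(nc$b, nc$a, x))
}

#' Write/read filter coefficients as CSV
#'
#' @param coef numeric coefficient vector.
#' @param path file path.
#' @return `read_filter_csv` returns the coefficient vector.
#' @export
write_filter_csv <- function(coef, path) {
  utils::write.csv(data.frame(tap = seq_along(coef) - 1L, coefficient = coef),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_filter_csv
#' @export
read_filter_csv <- function(path) {
  df <- utils::read.csv(path)
  df$coefficient[order(df$tap)]
}
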