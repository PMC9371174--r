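# Independent oracles used to cross-check the implementation.

# Closed-form impulse response of the DC blocker
# y[n] = a*y[n-1] + x[n] - x[n-1]: expanding the recurrence for a unit
# impulse gives {1, a-1, a(a-1), a^2(a-1), ...}.
dc_block_impulse_oracle <- function(alpha, n) {
  c(1, (alpha - 1) * alpha^(0:(n - 2)))
}

# Hand-packed SFLOAT: two's-complement nibble/12-bit packing done with
# plain arithmetic, independent of the codec under test.
sfloat_pack_oracle <- function(mantissa, exponent) {
  m <- if (mantissa < 0) mantissa + 4096 else mantissa
  e <- if (exponent < 0) exponent + 16 else exponent
  word <- e * 4096 + m
  as.raw(c(word %/% 256, word %% 256))
}

# Brute-force R-peak finder: argmax of the signal inside a window around
# each ground-truth beat time. Only valid for noise-free streams.
qrs_brute_force_oracle <- function(lead_ii, fs_hz, truth_times_s,
                                   half_window_s = 0.1) {
  vapply(truth_times_s, function(tt) {
    i0 <- max(1L, round((tt - half_window_s) * fs_hz) + 1L)
    i1 <- min(length(lead_ii), round((tt + half_window_s) * fs_hz) + 1L)
    as.integer(i0 - 1L + which.max(lead_ii[i0:i1]))
  }, integer(1))
}

# piecewise-constant schedule lookup, re-derived independently of the
# package internals
schedule_at_test <- function(schedule, t) {
  sch <- as.matrix(schedule)
  sch[max(1, findInterval(t, sch[, 1])), 2]
}

# frequency response magnitude of an FIR at frequency f
fir_response_oracle <- function(coef, f_hz, fs_hz) {
  n <- seq_along(coef) - 1
  abs(sum(coef * exp(-2i * pi * f_hz / fs_hz * n)))
}

ecg_lead2_filtered <- function(stream) {
  notch_filter(dc_block(stream$leads8[2, ]), stream$spec$mains_hz,
               stream$fs_hz)
}

warning_kinds <- function(warnings) {
  vapply(warnings, `[[`, character(1), "kind")
}

warning_times <- function(warnings) {
  vapply(warnings, `[[`, numeric(1), "timestamp")
}
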