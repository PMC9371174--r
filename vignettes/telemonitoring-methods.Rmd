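---
title: "Methods: simulating an SpO2/ECG telemonitoring chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating an SpO2/ECG telemonitoring chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phdsim)
```

## What the package models

`phdsim` is a pure-software re-creation of a personal-health-device
telemonitoring chain built around two IEEE 11073-style agents — a pulse
oximeter and a basic ECG device — reporting to a manager. Everything above
the acquisition hardware and below the user interface is modelled: the
signal chain that turns raw optical and electrode samples into saturation
and heart-rate values, the alarm rules that decide when a warning must be
raised, the pre-event buffering that preserves the waveform around an
event, the textual and binary wire formats, and the connection state
machines on both sides of the link. The radio itself (Bluetooth HDP) is
replaced by an in-memory pair of in-order channels, one reliable
(acknowledged) and one streaming, which is the property of the transport
the protocol actually relies on.

Because there is no hardware, the acquisition boards are replaced by
deterministic, seedable signal generators whose ground truth (true
saturation, true beat times) is recorded before any artefact is added.
Every downstream claim the test suite makes is a comparison against that
embedded truth.

## The synthetic signals

**PPG.** Each optical channel is `DC + a * w(t) + noise`, where `w` is a
zero-mean pulse waveform (a raised-cosine systolic peak at 30% of the beat
phase plus a smaller diastolic bump at 68%), `DC` is the baseline
absorbance, and `a` the pulsatile amplitude. The infrared amplitude is
`perfusion_ir * dc_ir` (default perfusion 5%, a typical finger perfusion
index); the red amplitude is chosen so that the ratio-of-ratios
`R = (AC/DC)_red / (AC/DC)_ir` maps to the requested saturation through the
calibration curve described below. Making `w` analytically zero-mean
matters: window means of the raw signal then estimate the DC level without
bias, which is what lets a noise-free stream round-trip to within 0.1% of
the target saturation.

**ECG.** Lead II is a sum-of-Gaussians PQRST template repeated at the
scheduled heart rate, R apex 1 mV. Template offsets and widths are fixed in
*absolute time* for the QRS complex (Q, R, S), matching the physiological
fact that QRS duration does not scale with rate, while the P and T
components shift and narrow with `sqrt(RR)` (Bazett-style QT shortening).
This choice is load-bearing: a template scaled uniformly with the R-R
interval changes the energy seen by the QRS detector's band-pass stage by
a factor of ~3 between 72 and 130 bpm, which is enough to stall a
half-of-peak threshold; with a fixed-width QRS the detector's operating
point is rate-independent. The remaining acquired leads (I, V1–V6) are
scaled copies of lead II — adequate because nothing downstream uses their
morphology, only the linear lead identities. R-apex times are snapped to
the sample grid and recorded as truth *before* baseline wander (0.3 Hz),
mains interference (50/60 Hz) and white noise are added.

**What the generator does not emulate:** ADC quantisation (bit depths are
metadata), electrode artefacts, muscle noise, arrhythmic morphology,
respiratory modulation of the PPG, and motion. Passing tests therefore
demonstrate correctness of the *processing chain and protocol logic* under
controlled conditions, not clinical robustness on real recordings.

## The signal chain

- **DC removal**: first-order IIR blocker `y[n] = a y[n-1] + x[n] - x[n-1]`,
  `a = 0.995`, a sub-0.5 Hz corner at both 500 and 1000 sps. Its step
  transient decays with time constant `1/(1-a)` samples, which is why beat
  detection ignores the first two seconds of a session.
- **PPG low-pass**: 51st-order (52-tap) Hamming-windowed FIR, 10 Hz cutoff,
  normalised to unity DC gain. At 1000 sps the Hamming transition band
  (~3.3/52 of fs ≈ 63 Hz) is much wider than the cutoff, so the response at
  10 Hz is only ≈ −1.7 dB rather than the −6 dB a textbook half-power
  reading would suggest; the stopband beyond ~60 Hz exceeds 40 dB. Both
  optical channels pass through the *same* filters, so the RMS ratio — and
  hence the saturation — is unaffected by the filter's in-band droop.
- **Mains notch**: a biquad with zeros exactly on the unit circle at the
  mains frequency and poles at radius 0.975. A steady mains tone is nulled
  (the finite-signal residual is the pole transient, which decays in
  ~40 samples); the ECG passband up to 40 Hz loses well under 1 dB.
- **QRS detection**: band-pass 5–15 Hz (3rd-order Butterworth, causal),
  differentiate, square, 150 ms moving-window integration, then an adaptive
  threshold at 0.5 × a running peak estimate with 0.8 per-beat decay and a
  200 ms refractory period. Detected integration peaks are mapped back to
  the R apex by an argmax over the preceding 250 ms of the input lead,
  which compensates the (rate-independent) group delay of the chain. On
  noise-free signals the result matches a brute-force truth-windowed argmax
  to within 2 samples.
- **Heart rate**: no value until five R-peaks have been seen; then
  `60000 / mean(last ≤5 R-R intervals in ms)`, rounded to integer bpm. The
  five-peak rule with a five-interval packet field is reconciled as: the
  first value uses the four available intervals, and the packet's five-slot
  R-R field is padded by repeating the oldest interval until five exist.
- **SpO2**: `R = (RMS(red_AC)/red_DC) / (RMS(ir_AC)/ir_DC)` over the window
  spanning the last three detected beats, emitted every third beat. The
  DC-normalised form is the default because a raw RMS ratio depends on the
  LED/detector gains and cannot yield a device-independent percentage; a
  `raw_ratio` flag provides the literal un-normalised mode. The calibration
  is a replaceable 256-entry look-up table sampling the standard empirical
  first-order curve `SpO2 = 110 − 25 R`, clipped to [0, 100] (so `R = 0.4`
  maps to 100% and `R = 1` to 85%); alternative tables load from a
  two-column CSV and must be non-increasing.

## Alarm rules and buffering

The desaturation rule evaluates the mean of the last 10 post-warm-up
values and fires strictly below 95%; the first 4 values of a session are
discarded. Evaluation waits for a *full* window — the discard rule exists
to suppress early false alarms, and evaluating partial windows would
reintroduce them. Rate warnings are strict inequalities: bradycardia below
60 bpm, tachycardia above 100 bpm, so 60 and 100 are normal. All alarms
are edge-triggered: one warning per excursion, re-armed when the monitored
quantity returns to the normal side of its bound (the cadence of repeated
warnings within one excursion is not specified by the modelled device, and
one-per-excursion is the least surprising choice).

Every heart-rate computation stores a buffer entry (rate, lead status,
timestamp, previous five R-R intervals, and the lead-II samples since the
previous entry); zero rates are never stored. The ring buffer evicts
entries older than 300 s relative to the newest, so it never holds more
than the five-minute pre-event window. On a warning, the event record
spans `[max(0, t − 300), t]` — from session start if the warning comes
early — and keeps appending live entries until `t + 300`, completing the
ten-minute record. Transmission interleaves per entry: one reliable packet
(rate, lead status, five R-R intervals, timestamp), then streaming packets
of 20 lead-II samples with a short final packet flushing any remainder.
Flushing (rather than carrying the remainder into the next entry's
packets) keeps per-entry sample conservation exact, which the tests check
bit-exactly.

## Wire formats

The textual dialect serialises `AGENT UPDATE <link> <handle> <attr>
<value>` with single spaces; handle `1` is the saturation numeric, `A`
(hex) the pulse-rate numeric, attribute `A4C` the observed value and `990`
the timestamp. Value tokens are `<mantissa>E<exponent>`. The timestamp
token is ISO-8601 with centiseconds; a compatibility formatter reproduces
the legacy form that omits the separator before the centisecond digits.

SFLOAT is the 16-bit medical float: high nibble the base-10 exponent, low
12 bits the mantissa, both two's complement, with the standard reserved
codes for NaN/±INF/NRes. APDUs use big-endian 16-bit kind and length tags
around kind-specific payloads. The layout is a self-contained dialect in
the spirit of MDER — interoperability with real 11073 stacks is not
claimed — with one deliberate deviation: streaming waveform samples are
IEEE-754 float64, not SFLOAT, because the conservation property
(reassembled waveform identical to the stored one, bit for bit) is worth
more in a simulator than wire-size realism. Scalar observations remain
SFLOAT-coded.

The pulse-oximeter configuration is *standard* (config id 0x0190, known to
managers a priori); the ECG configuration is *extended* (0x4001, in the
≥ 0x4000 extended space) and must be described through a
configuration-report exchange, which is exactly how the manager treats it.

## State machines and sessions

The agent moves through disconnected → associating → (configuring for
extended configs) → operating; acceptance with a known config skips the
configuring phase. An association response is honoured from both
`associating` and `unassociated`, so a stack that reports the request and
response in either order behaves identically. Any undefined (state, event)
pair raises a `protocol_violation` condition and leaves the state
unchanged; the tests enumerate the full product of states and events.
Alarm delivery over the reliable channel waits for the manager's ACK with
a 5 s simulated timeout and one retry before surfacing a delivery failure.
Time is discrete-event, driven entirely by sample timestamps; nothing
depends on the wall clock, which is what makes whole sessions bit-identical
across runs with the same seed.

Scenario construction pairs each stream with the warnings it must produce.
SpO2-centred scenarios (`rest`, `desaturation_event`) use PPG streams and
the pulse-oximeter agent; rate-centred ones (`exercise`,
`bradycardia_event`, `tachycardia_event`) use ECG streams and the ECG
agent. The event scenarios hold their excursions for 30 s — long enough
that the 10-value running mean and the 5-interval rolling rate must cross
their thresholds — and the expected warning windows account for the
measurement cadence (SpO2 every three beats; rate from a rolling mean that
needs two to three long/short intervals to cross a bound). The SpO2 agent
reports every measurement while associated, with warnings additionally
acknowledged; reporting only on alarm is available by flag, since the
modelled device's behaviour between alarms is not fully specified.

## Problem sizes and numerical choices

Unit tests use 5–30 s streams; the session tests run all five scenarios
(60–70 s each) at two seeds; the buffering check runs one ten-minute
session (300,000 samples at 500 sps) with an event near 400 s. Sample
indices are 1-based throughout, the native R convention; all exchanged
quantities are expressed in seconds, so no off-by-one can cross the API.
Heart rates are rounded to integer bpm before alarm comparison, matching a
transport that carries integer values. Ties in the beat detectors are
broken toward the earlier sample (`which.max`). Degenerate inputs are
defined, not exceptional: empty signals filter to empty signals, a
zero-perfusion stream yields a no-pulse marker rather than a saturation,
and a flat ECG yields an empty R-R series.

## Known limitations

- Lead morphology beyond lead II is schematic; only the linear lead
  identities are meaningful.
- The QRS detector is tuned for the generator's morphology plus moderate
  noise/wander/mains; it is not a validated clinical detector.
- The calibration curve is the standard textbook approximation; a real
  device would ship an empirically fitted table (which can be loaded from
  CSV).
- The transport does not model loss, reordering or latency; the resumable
  mid-transfer path is exercised only at the packetization level.
- No arrhythmia analysis beyond rate thresholds.
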