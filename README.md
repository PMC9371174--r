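# phdsim

Simulation of an IEEE 11073-style SpO2 and ECG telemonitoring pipeline in R.

Telemonitoring systems for cardiac rehabilitation pair wearable measuring
devices ("agents" in ISO/IEEE 11073 terms: a pulse oximeter, an ECG
recorder) with a collecting "manager" that receives values, waveforms and
warnings. Validating the logic of such a chain — filters, detectors, alarm
rules, buffering, wire formats, connection state machines — normally
requires acquisition hardware and volunteers. `phdsim` re-creates the whole
chain in software, replacing the acquisition boards with deterministic
synthetic signal generators that embed their own ground truth, so every
stage can be tested against a known answer.

## What it implements

**Signal generation** — two-channel photoplethysmograms (red + infrared)
with controllable DC level, pulsatile amplitude, pulse rate, target
saturation and noise; 8-lead ECG (I, II, V1–V6) built from a
sum-of-Gaussians PQRST template with scheduled heart rate, baseline
wander, 50/60 Hz mains interference and a lead-off schedule. Ground truth
(true SpO2, true R-peak times) is captured before artefacts are added.

**Signal chain** — first-order IIR DC blocker; 51st-order Hamming FIR
low-pass (10 Hz); biquad mains notch; Einthoven/Goldberger derivation of
the four limb leads (III = II − I, aVR = −(I+II)/2, aVL = I − II/2,
aVF = II − I/2); a variable-threshold QRS detector (band-pass 5–15 Hz,
derivative, squaring, 150 ms integration, adaptive threshold with per-beat
decay, 200 ms refractory); heart rate from the last ≤5 R-R intervals once
five peaks have been seen; and ratio-of-ratios pulse oximetry

    R = (RMS(AC_red)/DC_red) / (RMS(AC_ir)/DC_ir),   SpO2 = 110 − 25·R

computed every three beats through a replaceable 256-entry calibration
look-up table.

**Alarms and buffering** — desaturation when the mean of the last 10 SpO2
values falls below 95% (first 4 values of a session discarded);
bradycardia below 60 bpm; tachycardia above 100 bpm; all edge-triggered.
A ring buffer keeps five minutes of pre-event entries (rate, lead status,
timestamp, five R-R intervals, lead-II waveform) and event records span
five minutes before to five minutes after the warning.

**Protocol** — iWrap-style textual updates (`AGENT UPDATE FFFF 1 A4C
97E0`), MDER SFLOAT and a binary APDU dialect with exact round-trip
encoding; agent and manager connection state machines (standard
pulse-oximeter configuration vs. extended ECG configuration with a
configuration-report exchange); event transmission as one reliable packet
per buffer entry followed by streaming packets of 20 lead-II samples, over
an in-memory reliable + streaming two-channel transport.

## Worked example

```r
library(phdsim)

sc  <- make_scenario("desaturation_event", seed = 1L)  # SpO2 dips to 88%
res <- run_session(sc)

nrow(res$record$measurements)
#> [1] 57
head(subset(res$record$measurements, kind == "spo2_pct"), 4)
#>     time     kind value
#> 1  5.058 spo2_pct    97
#> 3  7.458 spo2_pct    97
#> 5  9.857 spo2_pct    97
#> 7 12.258 spo2_pct    97

w <- res$record$warnings[[1]]
sprintf("%s at t=%.1f s, value=%.0f, acknowledged=%s",
        w$kind, w$timestamp, w$value, w$acknowledged)
#> [1] "desaturation at t=36.3 s, value=88, acknowledged=TRUE"

build_iwrap_update(round(w$value), "spo2")
#> [1] "AGENT UPDATE FFFF 1 A4C 88E0"
```

The manager receives saturation and pulse values every three beats while
the agent is associated (97% at rest here); once the scenario's embedded
dip to 88% has pushed the 10-value running mean below 95%, the alarm
engine raises a desaturation warning, which is delivered on the reliable
channel and acknowledged by the manager.

A shell front end wraps the same functions:

```sh
Rscript inst/cli/phdsim simulate --scenario bradycardia_event --seed 1 --out out/
Rscript inst/cli/phdsim decode --kind iwrap "AGENT UPDATE FFFF A A4C 74E0"
```

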