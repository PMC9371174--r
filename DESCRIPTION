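Package: phdsim
Title: Simulation of an IEEE 11073 SpO2 and ECG Telemonitoring Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pure-software re-creation of a personal-health-device
    telemonitoring chain: deterministic synthetic photoplethysmogram (PPG)
    and electrocardiogram (ECG) generators with embedded ground truth, the
    agent-side signal chain (DC blocking, FIR low-pass and mains-notch
    filtering, variable-threshold QRS detection, heart-rate computation,
    ratio-of-ratios SpO2 estimation with a replaceable calibration
    look-up table, 8-to-12 lead derivation), desaturation and
    bradycardia/tachycardia alarm logic with a pre-event ring buffer and
    ten-minute event records, wire-format codecs (an iWrap-style textual
    dialect, MDER SFLOAT, and a binary APDU framing), and agent/manager
    connection state machines over an in-memory reliable-plus-streaming
    two-channel transport.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
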