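Package: gaitwave
Title: Self-Calibrating Real-Time Gait-Event Detection from Leg Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects heel-strike and toe-off gait events in tri-axial leg
    accelerometer recordings in real time. A short observation window at the
    start of walking is analysed with a Morlet continuous wavelet transform of
    the smoothed jerk magnitude to self-calibrate amplitude and duration
    thresholds, which then drive a streaming peak-confirmation state machine.
    Includes a force-sensitive-resistor (FSR) reference event extractor,
    precision/recall/F1 and Bland-Altman timing-agreement evaluation, and a
    synthetic gait simulator with programmed ground truth for level-ground and
    stair walking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
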