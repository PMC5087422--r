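# gaitwave

Self-calibrating, real-time detection of **heel-strike (HS)** and
**toe-off (TO)** gait events from a single tri-axial leg accelerometer, with
a force-sensitive-resistor (FSR) reference extractor, an evaluation suite
(precision/recall/F1 and Bland–Altman timing agreement), and a synthetic
gait simulator for testing on level ground, up-stairs and down-stairs
walking.

The package is for researchers in wearable-sensor gait analysis who need
per-stride event timing without foot switches: rehabilitation monitoring,
fall-risk screening, prosthetics/orthotics control, and anyone validating an
event detector against programmed ground truth.

## The method

All detection operates on the smoothed jerk magnitude of the high-pass
filtered acceleration (units g/s; `fs` = 148.15 Hz by default):

```
cAcc(n) = sqrt(ax² + ay² + az²)                      (walking onset: first cAcc > TH₁ = 1 g)
Jerk(n) = sqrt((dax/dt)² + (day/dt)² + (daz/dt)²)
J(n)    = trailing mean of Jerk over m = 30 samples
```

Amplitude thresholds cannot be fixed a priori — stride intensity differs
strongly across terrains — so the detector **self-calibrates** on a
300-sample observation window that starts at the walking onset:

1. Morlet CWT `W_n(s)` of the centred window on integer scales `s = 1..241`,
   where scale maps to frequency as `f = f_c·F_s / s` with `f_c = 0.8125` Hz
   (so 1.6 Hz → s = 75, 0.8 Hz → s = 150, 0.5 Hz → s = 241).
2. Scale-energy spectrum `E_s = Σ_n |W_n(s)|²`, cross-correlated against the
   two-Gaussian prior
   `E⁻_s = exp(−((s−75)/15)²) + exp(−((s−150)/25)²)` to get the scale delay
   τ; the spectrum valley `s_λ` then splits event from cycle scales, and the
   posterior event/cycle scales are the per-side argmaxes.
3. The coefficient rows at those scales (`x_e`, `x_c`, low-pass filtered at
   10 Hz) segment the window at the negative peaks of `x_e`; each region's
   event is the argmax of `J`, classified HS/TO by the sign of the dominant
   `x_c` extremum.
4. The window events yield the running thresholds: baseline
   `TH₂ = median(J)`, mean HS peak `TH₃`, mean TO peak `TH₄`, and mean
   swing/stance durations `T_swin`, `T_std`.

Streaming then proceeds one sample at a time: a local peak of `J` above
`r_b·TH₂` (r_b = 0.8) opens a 15-sample confirmation wait (any larger sample
restarts it); a confirmed candidate is accepted as the next event — kinds
strictly alternate — iff its amplitude exceeds `r₁·TH₃` (HS) or `r₁·TH₄`
(TO) **and** the time since the previous event exceeds `r₂·T_swin` (before
HS) or `r₂·T_std` (before TO), with `r₁ = r₂ = 0.5`. Events are timestamped
at the peak; the decision latency (wait + smoothing group delay, ≈ 200 ms at
the defaults) is reported separately.

## Worked example

```r
library(gaitwave)
trial <- generate_trial(terrain_presets()$level, duration = 12, seed = 1)
fit <- gait_detect(trial)   # preprocess -> calibrate -> stream -> evaluate
summary(fit)
```

```
Gait-event detection fit (1778 samples @ 148.15 Hz)
Walking onset: sample 299 (2.01 s)
<gait_calibration: window [299, 598] @ 148.15 Hz>
<scale_estimate: tau = -10, split = 91, event scale = 70, cycle scale = 126>
  4 window events (HS TO HS TO)
<threshold_set>
  TH2 (baseline)   : 33.792 g/s
  TH3 (HS peaks)   : 70.216 g/s
  TH4 (TO peaks)   : 49.340 g/s
  T_swin / T_std   : 0.418 / 0.685 s
  r_b / r1 / r2    : 0.80 / 0.50 / 0.50
Streaming latency: 199 ms (median)

Against FSR reference:
    kind TP FP FN precision recall f1
1     HS  7  0  0         1      1  1
2     TO  7  0  0         1      1  1
3 pooled 14  0  0         1      1  1
```

Reading this: walking starts 2.01 s into the trace; the calibration window
finds four alternating events whose scale estimates (event scale 70 ≈
1.72 Hz, cycle scale 126 ≈ 0.95 Hz) match the simulated cadence of 0.9
strides/s; the estimated swing (0.418 s) and stance (0.685 s) recover the
programmed 38%/62% split of the 1.11 s cycle; and every post-window HS and
TO is found against the FSR reference (F1 = 1.00) with a consistent ~220 ms
detection delay, dominated by the 30-sample jerk smoothing plus the
15-sample confirmation wait.

`events(fit)` returns the event table (`kind`, sample `n`, time `t`,
amplitude, latency); `plot(fit)` draws `J(n)` with the window shaded and
events marked; `plot(fit$evaluation$timing)` gives the Bland–Altman plot.

A command-line front end with `simulate`, `detect`, `fsr-events`,
`evaluate`, `run` and `sweep` subcommands is installed at
`inst/cli/gaitwave.R`.

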