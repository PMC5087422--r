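---
title: "Self-calibrating gait-event detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-calibrating gait-event detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwave)
```

## The detection model

A walking leg produces two sharp acceleration transients per gait cycle:
one at heel strike (HS), when the foot hits the ground, and one at toe off
(TO), when it leaves. Both are far more visible in the *jerk* — the time
derivative of acceleration — than in the acceleration itself, because
differentiation amplifies the transient relative to the smooth swing
motion. The package therefore reduces the tri-axial signal to a single
non-negative trace, the smoothed jerk magnitude `J(n)`, and treats event
detection as peak detection on `J`.

The difficulty is that the peak amplitudes change strongly with terrain
(stair descent impacts are much harder than stair ascent), so no fixed
threshold works. The detector instead *self-calibrates per trial*: a
300-sample observation window (~2 s, a little more than one gait cycle at
normal cadence) at the start of walking is analysed in the time–frequency
plane to locate the window's own events, and the thresholds for the
subsequent streaming phase are derived from them.

Assumptions worth stating explicitly:

* walking is roughly periodic during the observation window (no abrupt
  speed changes there);
* the window contains at least one event of each kind and at least one
  swing and one stance interval — otherwise calibration raises an error
  rather than guessing;
* HS transients carry more energy than TO transients, which is what lets
  the cycle-band phase distinguish the two kinds;
* each trial starts from quiet rest, so a 1 g composite-acceleration
  threshold marks the walking onset cleanly.

### Time–frequency calibration

The smoothed jerk in the window is transformed with a Morlet CWT on the
integer scale grid `1..241`. With centre frequency `fc = 0.8125` Hz the
scale–frequency map `f = fc * fs / s` puts an assumed event rate of 1.6 Hz
at scale 75, a cycle rate of 0.8 Hz at scale 150, and a minimum gait
frequency of 0.5 Hz at the top of the grid (241). The per-scale energy
`E[s]` of the window is cross-correlated with a two-Gaussian prior centred
at (75, 150) with spreads (15, 25); the best lag `tau` shifts the prior to
the subject's actual cadence, the energy valley inside the shifted interval
splits event scales from cycle scales, and the per-side argmaxes give the
posterior event and cycle scales. The real parts of the coefficient rows at
those two scales (`x_e`, `x_c`) then segment and label the window: negative
peaks of `x_e` bound one region per event, the argmax of `J` inside a
region is the event sample, and the sign of the dominant `x_c` extremum in
the region gives its kind (positive = HS). Thresholds follow: `TH2` =
median of `J` over the window, `TH3`/`TH4` = mean HS/TO peak amplitude, and
`T_swin`/`T_std` = mean swing/stance interval.

### Streaming phase

After the window, one sample is processed at a time. A local peak of `J`
above `r_b * TH2` opens a 15-sample confirmation wait; any sample that
beats the current candidate restarts the wait with the larger peak; a
candidate that survives the wait is accepted as the next event — kinds
strictly alternate — iff it passes the amplitude gate (`r1 * TH3` or
`r1 * TH4` depending on the expected kind) and the duration gate
(`r2 * T_swin` or `r2 * T_std` since the previous event). Rejected
candidates are discarded and the search resumes at the next sample, which
keeps the state machine constant-memory and strictly causal. Events are
timestamped at the confirmed peak; the decision itself happens `wait_len`
samples later, and the reported per-event latency adds the group delay
`(m-1)/2` of the jerk smoothing, ≈ 199 ms in total at the defaults.

## Parameters

| name | default | units | role |
|---|---|---|---|
| `fs` | 148.15 | Hz | sampling rate; all sample-count parameters assume it |
| `hp_cutoff`, `hp_order` | 0.5, 2 | Hz, – | zero-phase Butterworth high-pass removing gravity/drift |
| `th1` | 1 | g | onset threshold on the filtered composite acceleration |
| `smooth_m` | 30 | samples | trailing-mean window on the jerk (~0.2 s): suppresses ripple inside a transient at the cost of latency |
| `window_len` | 300 | samples | observation window (~2 s, > 1 cycle at 0.5 Hz minimum gait frequency) |
| `fc`, `s_max` | 0.8125, 241 | Hz, – | Morlet centre frequency and scale-grid top |
| `prior_mu_e/mu_c/sigma1/sigma2` | 75/150/15/25 | scales | two-Gaussian scale prior |
| `band_cutoff` | 10 | Hz | zero-phase low-pass on `x_e`, `x_c` |
| `wait_len` | 15 | samples | confirmation wait (~100 ms): longer is more reliable but adds latency |
| `r_b`, `r1`, `r2` | 0.8, 0.5, 0.5 | – | baseline, amplitude and duration membership fractions |
| `match_tolerance` | 0.4 | s | evaluation-only: event matching window, wide enough for the ~0.2 s detection delay yet below the same-kind event spacing at normal cadence |

`sweep_memberships()` re-runs the synthetic corpus over a grid of `r1`,
`r2` values for anyone revisiting the membership defaults.

## The synthetic generator

`generate_trial()` emulates the structure the detector relies on, not
biomechanical waveforms: a quiet lead-in (gravity plus sensor noise), then
gait cycles at a jittered cadence, each placing an HS burst at the cycle
start and a TO burst at the end of stance (62% of the cycle by default).
A burst is a damped sinusoid at 8 Hz with a 0.18 s decay constant and
0.45 s support, projected on fixed direction cosines — an impact transient
that rings for two to three oscillations, as shank-mounted sensors record.
Burst peak amplitudes are terrain presets: level 3.5/2.4 g (HS/TO), up
stairs 2.8/2.3 g, down stairs 4.5/3.0 g, ordered so stair descent impacts
hardest and ascent most gently; HS always exceeds TO, which is what makes
separate `TH3`/`TH4` thresholds meaningful. FSR channels are trapezoids
keyed to the same times (heel loading starts at HS; toe unloading completes
at TO), so the FSR reference rules have exact programmed crossings to
recover.

The burst scale matters more than it may appear: additive white
acceleration noise of σ = 0.05 g per axis becomes, after differentiation at
148.15 Hz and 30-sample smoothing, a jerk-magnitude floor of roughly
17 g/s with excursions to ~21 g/s. Event peaks must clear twice that floor
for the default membership gates (`r1 = 0.5`) to separate events from
noise, which the chosen burst model provides — matching the qualitative
morphology of real smoothed-jerk recordings, where event peaks stand
several-fold above baseline.

What the generator does **not** emulate: double-support asymmetries,
stride-to-stride waveform variability beyond cadence jitter, sensor
saturation and orientation drift, pathological gait, or speed changes
within a trial. Passing tests on this corpus therefore demonstrate that the
algorithm recovers events whose timing/amplitude structure matches its
model class — not clinical-grade performance on arbitrary real recordings.

## Numerical choices

* **Window centring before the CWT.** The transform uses zero-padded
  boundaries, and `J` has a large positive offset; uncentred, that offset
  acts as a boxcar whose edges flood the large scales with spurious energy
  and bias the scale-delay estimate upward. The window mean is therefore
  subtracted before the transform (the Morlet is zero-mean, so this changes
  no oscillatory content); amplitudes and the median baseline are computed
  from the uncentred signal.
* **Zero-phase filtering.** Both Butterworth filters are applied forward and
  backward with odd-reflection padding and steady-state initial conditions,
  so a constant input produces the exact DC response with no startup
  transient; the effective magnitude response is the square of the
  single-pass response (amplitude 0.5 at the cutoff).
* **CWT kernel truncation.** The Morlet kernel is cut at `|eta| = 8`, where
  its Gaussian envelope is ~1e-14, so the FFT-convolution implementation
  agrees with the literal summation definition to ~1e-9; coefficients carry
  a `1/sqrt(s)` normalisation for comparable magnitudes across scales.
* **Discrete derivative.** The jerk uses the causal backward difference
  scaled by `fs`, with sample 1 defined as 0 — real-time operation forbids
  central differences.
* **Smoothing warm-up.** During the first `m-1` samples the trailing mean
  divides by the number of samples seen, avoiding a startup ramp that could
  fake an onset.
* **Rounding and ties.** Printed scales use round-half-up (reproducing
  75/150/241); all argmax/argmin ties break to the smallest index; a peak
  plateau belongs to its first sample; equal-amplitude candidates during
  the confirmation wait keep the first occurrence.
* **Degenerate inputs.** An all-zero trace flows through preprocessing as
  zeros with an absent onset; an all-zero energy spectrum, a window without
  negative event-band peaks, or a window missing an event kind or pair type
  raise errors naming exactly what is missing.

## Design decisions on genuinely open points

* **Band filter direction.** The calibration step calls for filtering
  `x_e`/`x_c` at 10 Hz "to remove high-frequency noise" while naming a
  high-pass; a high-pass at 10 Hz would erase the 1–2 Hz bands entirely.
  The low-pass reading is implemented as the default, with
  `band_filter = "highpass"` available for the literal one.
* **Real part, not modulus.** Region segmentation needs *negative* peaks,
  and kind classification needs a sign; the complex modulus has neither,
  so the bands are real parts of the CWT rows.
* **Window-event baseline gate.** The segmentation rule assigns an event to
  every region, including the partial regions at the window edges. An edge
  region that contains no true event would contribute a spurious
  low-amplitude "event" that corrupts the threshold averages and — worse —
  flips the expected-kind alternation for the whole streamed remainder. The
  window detector therefore applies the same baseline membership the
  streaming phase uses (peak > `r_b * median(J)`), reusing the algorithm's
  own definition of a non-event peak.
* **Window-event amplitude consistency.** Even past the baseline gate, a
  partial edge region can contribute a noise peak as a spurious event. Each
  window event is therefore checked against the streaming phase's own
  stride-amplitude membership, leave-one-out: an event at or below
  `r1 x` the mean amplitude of the *other* events of its kind could never
  be accepted by the stream and is dropped (falling back to the unfiltered
  set if that would leave the window uncalibratable).
* **Alternation repair.** If window classification still yields two
  consecutive events of one kind, the lower-amplitude one is dropped before
  thresholds are computed, since the swing/stance averages presuppose
  alternation.
* **Toe-off FSR rule.** "A 5% decrease in the maximum toe amplitude" is
  read as the signal falling below 95% of its window maximum, mirroring the
  5%-rise heel rule; `toe_rule = "below_5"` selects the alternative
  reading (below 5% of the maximum).
* **Indexing.** Sample indices are 1-based throughout, the R convention;
  times in seconds (`t = (n-1)/fs`) are the interchange currency and are
  unaffected.
* **No rejection timeout.** A long run of gate rejections (conceivable
  under gross miscalibration) could stall the expected-kind bookkeeping;
  the streaming contract is kept minimal and no relaxation timeout is
  added, matching the single-window calibrate-once design.

## Evaluation conventions

Detected and reference events are matched greedily nearest-in-time,
one-to-one, same kind only, within 400 ms; matched pairs are true
positives, the rest false positives/negatives, and F1 is reported per kind
and pooled. The final reference gait cycle of each trial is excluded from
scoring, since a trace that ends mid-cycle cannot be scored fairly. Timing
agreement reports the mean and absolute-mean difference with SDs, the
Bland–Altman limits `MD ± 1.96 SD`, and a normal-theory 95% CI of the mean
difference `MD ± 1.96 SD / sqrt(n)`.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
12-s trials at 148.15 Hz (~1 778 samples), a 300 × 241 scalogram per
calibration, corpora of 3 terrains × 10 seeds for accuracy floors and 10
seeds per noise level for the degradation property; brute-force oracles
(dense CWT summation, exhaustive event assignment) are kept to ≤ 40-sample
signals and ≤ 8-event lists. The full suite runs in well under a minute on
one CPU.

## Known limitations

* Calibration hinges on one observation window; it is not re-estimated
  during long walks, so cadence drift degrades the duration gates.
* The kind classifier depends on HS bursts out-powering TO bursts; gait
  styles that violate this (e.g. some shuffling patterns) would swap
  labels systematically.
* The ~200 ms detection latency (smoothing + confirmation wait) is
  inherent to the parameter defaults; applications needing faster triggers
  must shorten `smooth_m`/`wait_len` and accept noisier peaks.
* White-noise robustness is bounded: beyond σ ≈ 0.1 g the differentiated
  noise floor approaches the gate levels and accuracy degrades, as the
  monotone-degradation test documents.
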