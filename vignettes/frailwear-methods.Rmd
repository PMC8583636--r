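---
title: "Methods: signal models and detection algorithms in frailwear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal models and detection algorithms in frailwear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailwear)
```

frailwear implements the signal-processing core of a wearable platform for
frail and pre-frail adults: a two-stage fall detector fed by a lower-back
accelerometry patch, exercise monitoring from a thorax-worn smart vest
(repetition counting, activity discrimination, metabolic expenditure), a
respiratory channel with motion-artifact gating, and the smartwatch alert
logic. This vignette explains the models behind each stage, the tunable
parameters, the design decisions taken where the problem was genuinely
open, and what the synthetic validation does and does not demonstrate.

## Coordinate convention and personalization parameters

All streams are triaxial accelerations at 40 Hz, in m/s². The device x axis
is aligned with the trunk-longitudinal axis when standing, so upright rest
gives `ax ≈ 9.81` and lying gives `ax ≈ 0`. Orientation calibration of a
real device is out of scope; the convention is fixed by the generators.

`detector_config()` carries the per-subject device parameters with their
published defaults:

| parameter | default | units | role |
|---|---|---|---|
| vertical posture threshold | 6.5 | m/s² | trunk-axis gravity projection at/above which a segment is upright |
| fall energy threshold | 0.079 | m²/s⁴ | windowed variance an impact must exceed |
| horizontal posture threshold | 2.5 | m/s² | projection at/below which a segment is lying |
| movement activity energy threshold | 0.1490 | m²/s⁴ | exercising vs not; fixes the cycle amplitude floor |
| resting energy threshold | 0.0306 | m²/s⁴ | rest masking for counting and the 1-MET floor |
| ascending / descending displacement threshold | +0.1 / −0.12 | m | climb tag / fall displacement criterion |
| intense motion artifact threshold | 3.7 | m/s² | respiratory artifact gate, applied to \||a|−g\| |

Anthropometric parameters (weight, birth date, gender, height, thorax
perimeter) have **no defaults**; `estimate_met()` refuses to run without a
configured weight.

## Two-stage fall detection

**Stage 1 (on-device)** computes a windowed energy statistic: the variance
of the acceleration magnitude over a centered 0.5 s (21-sample) window, in
m²/s⁴ — the units of the published energy thresholds, which is what
identifies variance of acceleration as the intended statistic. The original
device's impact statistic is published elsewhere and was not available;
the choice here is isolated behind `signal_energy()` so it can be swapped.
Local maxima of the energy series above the fall energy threshold become
candidate impacts; a 4 s refractory period keeps only the strongest of any
cluster (one fall with bounces must produce one candidate). Each candidate
is shipped as a window of 2 s before to 2 s after the impact sample
(161 samples at 40 Hz; boundary-clipped windows are flagged `truncated`).
The 20-byte block framing of the original BLE transport is emulated by
`pack_frames()` / `unpack_frames()` (16-bit fixed point, ±16 g full scale).

**Stage 2 (gateway)** classifies each window with a conjunction built from
exactly the published parameter set:

* impact energy ≥ fall energy threshold,
* pre-impact posture (first 1 s of the window) vertical,
* post-impact posture (last 1 s) horizontal,
* net vertical displacement ≤ −0.12 m.

Posture is the mean trunk-axis projection; between the two thresholds the
nearer class wins and the exact midpoint (4.5 m/s²) resolves to vertical,
which makes the pre-posture check conservative against false alarms. The
conjunction is what separates an abrupt sit-down (real downward
displacement, but posture stays vertical) or lying down (posture change,
but no impact energy) from a fall. Post-impact immobility is deliberately
not a criterion: people who try to stand up after a fall would otherwise
become false negatives.

### Vertical displacement estimation

The vertical acceleration is taken as `|a| − g`: during partial free fall
the magnitude drops below gravity, and the impact deceleration restores
it. Net displacement is its double integral, which is exquisitely
sensitive to drift, so three controls are applied:

1. the impact is re-centered on the magnitude-deviation peak inside the
   window (the stage-1 energy maximum can sit mid-descent), and the
   integration is restricted to a tight active interval (0.85 s before to
   0.35 s after the peak) that covers descent and impact;
2. a baseline, estimated on the quiet flanks of the window from a 0.8 s
   moving-average of the signal and interpolated linearly across the
   active interval, is subtracted before integration;
3. the velocity is anchored by pinning its smoothed flank means to zero
   with a linear ramp (the subject stands quietly before the descent and
   lies quietly after the impact).

A least-squares linear detrend of the velocity over the whole window — the
textbook-looking alternative — is *not* used: the integral of least-squares
residuals is identically zero, so it would annihilate the very
displacement being measured. The flank-anchored construction preserves a
genuine fall's drop while leaving only the bounded oscillatory term for
zero-mean periodic accelerations and suppressing slow drift.

## Sawtooth parameterization and activity monitoring

Both exercise accelerometry and the respiratory channel are sawtooth-like
cyclic waveforms, and one engine segments both: alternating-extrema
tracking with amplitude hysteresis. A reversal is committed only after the
signal retraces the hysteresis floor from its running extremum; a cycle is
trough → peak → trough. For accelerometry the floor derives from the
movement activity energy threshold as twice the peak-to-trough amplitude
of a sinusoid whose variance equals that threshold
(`2·√(2·0.149) ≈ 1.09 m/s²`): oscillations the device would not call
movement cannot be repetitions.

The dominant axis is the one with the largest band-power in the 0.2–3 Hz
cadence band. The segmentation signal itself is band-passed 0.08–3 Hz: the
slowest maintenance exercises run at 4–5 s per cycle (0.2–0.25 Hz), and a
high-pass at 0.2 Hz would sit on their fundamental and clip amplitudes
near the hysteresis floor. The high-pass leg is implemented as
moving-average subtraction: at normalized cutoffs of a few 10⁻³ an IIR
high-pass is numerically fragile, while the moving average is exact and
phase-free.

`count_repetitions()` takes the exercise as given (on the device the user
selects it before starting) and applies two acceptance filters: cycle
periods must lie within 0.45–2.2 of the exercise's template cadence, and
cycles peaking inside resting segments (mean squared dynamic acceleration
over 1 s below the resting threshold) are excluded.
`classify_activity()` is a cross-check, not the counting gate: it matches
the measured feature vector (dominant axis, median period, median
amplitude, rise/fall asymmetry) against a bank of per-exercise reference
features. The bank is measured on noiseless generator exemplars with the
same pipeline, so classifier and input see identical filtering bias.

**Metabolic expenditure** uses 10 s actigraphy epochs (the shortest epoch
spanning several cycles of the slowest exercises). Epoch activity counts
are the mean band-passed dynamic vector magnitude `√(bx²+by²+bz²)`; MET is
linear in counts, anchored at 1 MET for rest and 3.5 MET at the reference
walking level (0.64 m/s², the mean rectified amplitude of the walking
template), floored at 1 MET when the epoch energy is below the resting
threshold. Energy rate is `MET × 3.5 × weight / 200` kcal/min and the
cumulative expenditure is the trapezoidal time integral. The linear
mapping and its anchor are this package's own definition — the platform
publishes the output quantity but not a formula. Epochs whose net vertical
displacement (raw `|a|−g`, endpoint-ZUPT) exceeds +0.1 m are tagged
`ascending`; over a 10 s epoch this double integral is indicative rather
than metric, so the tag does not change the MET value.

## Respiration

The capacitive expansion signal is segmented by the same cycle engine with
two respiratory specifics: no band-pass (controlled breathing may be as
slow as 4 breaths/min, below any band that also suits exercise), and a
hysteresis floor relative to the signal's own 5–95 % amplitude range
(20 %), which makes the segmentation invariant under positive rescaling of
the arbitrary capacitance units. Rising flank = inspiration; cycles
shorter than 1 s (above the 60 breaths/min physiological ceiling) are
rejected as micro-cycles.

Each cycle also carries a `flank_ref`: the time its inspiratory flank
crosses half-amplitude, linearly interpolated. The flank is the steepest
part of the cycle, so this reference jitters an order of magnitude less
under slow baseline wander than the flat troughs do;
`evaluate_breathing_protocol()` estimates segment rates from flank-ref
spacings (and attributes cycles to protocol segments by their midpoint, so
boundary-trough jitter cannot move a cycle into the wrong segment).
`respiratory_rate()` itself reports 60 over the mean duration of the
non-gated cycles in a trailing window, as the device does.

Any cycle overlapping an interval where the concurrent acceleration
magnitude deviates from static gravity by more than 3.7 m/s² is flagged
`artifact_gated` and never contributes to a rate: the table gives an
acceleration for this gate, and deviation from static gravity is the
natural artifact measure for it.

## The alert state machine

Time is injected (`now`, `tick()`), never read from a clock, so every
behavior is deterministic and enumerable. A confirmed fall moves the
machine to `fall_prompt`; a response before the deadline resolves it
(`help_needed` → alert with trigger `fall_confirmed`, `ok` → cancelled);
an unanswered prompt always escalates to `alert_sent(fall_auto)` — the
subject may be unconscious. Manual SOS requires a 3 s press-and-hold and a
cancellable countdown. The deployed prompt and countdown durations are
unreported, so they are configurable with defaults of 30 s and 5 s,
flagged as package defaults in the config schema. The test suite
model-checks reachability: `alert_sent` is unreachable except through a
fall prompt or an armed SOS countdown, and every prompt timeline resolves
by its deadline.

## The synthetic generators: what they emulate

No recorded dataset exists for this platform, so the generators replicate
the laboratory validation protocol with kinematic templates plus noise,
and every downstream stage is tested against their ground truth.

* **Falls** are gravity-reorientation events: upright rest, a partial
  free-fall descent (hann-shaped magnitude dip, 0.5–0.6 s), an impact
  spike sized to return the velocity to zero (peak magnitudes ≈ 35–42
  m/s²), and lying rest, with the gravity vector rotating from the trunk
  axis to the z axis. The implied drops are 0.46–0.70 m depending on the
  fall type, all well past the −0.12 m criterion. All three protocol falls
  (to the knees, from a chair, from a bench standing in for a bed) start
  trunk-vertical, as the protocol performs them.
* **Fall-free activities** at the lower-back site are modeled as
  orientation sway (walking, stairs) and smooth posture excursions
  (picking an object up: a 70° bend; sitting down: a small recline with a
  gentle seat-contact burst). The near-center-of-gravity sensor site is
  specifically robust to motion artifacts, which is why locomotion there
  is orientation-dominated with the magnitude pinned at gravity.
* **Exercises** at the thorax are asymmetric smoothed-triangle cycles on a
  per-exercise dominant axis, with periods of 1.6–5 s, amplitudes of
  1.8–3.2 m/s² and per-exercise rise fractions; walking is 100 steps/min
  and cycling 60 strokes/min. These cadences and amplitudes are stated
  assumptions in the range of elderly maintenance exercise — the source
  protocol reports none.
* **Breathing** is a raised-cosine inspiration (40 % of the cycle)
  followed by a raised-cosine expiration; the validation ramp steps
  6 → 10 → 12 → 15 → 20 → 30 breaths/min with three cycles per step, every
  period an integer number of samples so that noiseless recovery is exact.
* **Noise** is band-limited Gaussian: white noise smoothed by a 3 s moving
  average and rescaled to the requested marginal sd. This models slow
  postural sway and baseline wander, the dominant residual variability of
  a body-worn sensor (the accelerometer's electronic noise floor is
  ~0.002 g, negligible at these scales). Band-limitation matters: white
  noise at the 0.3 m/s² validation level would alone contribute
  ≈ 0.09 m²/s⁴ of windowed variance — above the 0.079 m²/s⁴ impact
  threshold — which would contradict the device's observed behavior of
  never triggering during ordinary walking.

The validation conditions used by the acceptance script and tests are:
3 subjects × 3 repetitions of the 8-activity sequence (27 falls, 45
fall-free instances) at noise 0.3 m/s²; 6 repetitions of each of the 15
static exercises and 20 seeded one-minute walking/cycling runs at the same
noise; the noiseless breathing ramp, plus a 0.05-amplitude-unit noisy ramp
for the rate-error bound (the capacitive channel is a clean, high-
sensitivity signal; 5 % is a conservative noise allowance for it). These
sizes mirror the original laboratory session.

## What passing tests do and do not show

The synthetic streams exercise every feature the detectors use — posture
transitions, energy transients, displacement, cadence, cycle asymmetry,
artifact bursts — under seeded noise, and recovery is exact at zero noise
by construction. They do **not** contain soft-tissue artifacts, sensor
detachment, orientation miscalibration, inter-subject movement
variability, BLE packet loss, or real respiratory pathology; perfect
scores here demonstrate the correctness and self-consistency of the
processing chain under the stated signal models, not clinical
performance. Likewise the MET mapping is anchored by definition, the
ascending tag is indicative only, and the activity classifier is validated
against generator exemplars, not against human movement corpora.

## Numerical and degenerate-input choices

* Energy windows shrink at stream edges; windows shorter than 2 samples
  have zero variance. The magnitude is centered before the prefix-sum
  variance so the arithmetic stays well conditioned around 9.81.
* Streams shorter than one energy window yield an empty impact list, not
  an error; truncated impact windows are emitted flagged, classified on
  the computable criteria, and marked low-confidence.
* Filtering uses odd-reflection padding at both ends so neither filter
  leg rings at stream boundaries.
* Extrema ties resolve to the first attaining sample; a trailing trough is
  closed at end-of-stream when the descent from the last committed peak
  has already retraced the hysteresis floor.
* The posture midpoint tie (4.5 m/s²) resolves to vertical.
* All generators are seeded and bit-reproducible; the protocol generator
  derives per-stream seeds from its master seed.
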