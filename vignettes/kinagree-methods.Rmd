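---
title: "Models and methods behind kinagree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinagree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinagree)
```

`kinagree` quantifies how well a wearable inertial sensor system agrees
with an optical motion-capture reference when both measure active shoulder
movements. This vignette documents the models, estimators, defaults and
design choices, so that results can be interpreted — and the package's
assumptions challenged — without reading the source.

## Rotations and the XZ′Y″ Euler convention

Shoulder orientation is the rotation of the humerus frame relative to the
thorax frame. Both measurement systems express it as a Tait–Bryan XZ′Y″
Euler decomposition: first a rotation about X (frontal plane,
abduction/adduction), then about the rotated Z′ (sagittal plane, vertical
flexion/extension), then about the twice-rotated Y″ (transverse plane,
axial rotation and horizontal movements).

Two choices are not dictated by the convention's name and had to be fixed:

* **Intrinsic (rotating-axes) composition.** The matrix is
  `R = Rx(x) · Rz(z) · Ry(y)`, the standard choice in upper-limb motion
  analysis. An extrinsic reading would permute the factors; nothing
  downstream would detect the difference on single-plane movements, but the
  multiplanar pattern would change, so the choice is documented and frozen.
* **Signs.** Positive X = abduction, positive Z = vertical flexion,
  positive Y = external rotation / horizontal extension. Adduction,
  vertical extension, internal rotation and horizontal flexion are negative
  excursions of the same channels. Outcomes are reported as magnitudes, so
  the sign convention matters only inside the simulator and for reading raw
  channel plots.

The middle angle z′ lives in [−90°, 90°]. At |z′| = 90° (gimbal lock) the
outer angles are not separately identifiable; `euler_from_rotation()` then
sets y″ = 0, folds the identifiable combination into x, and flags the
sample. The tie-break is arbitrary but deterministic, so it can be tested:
recomposition still reproduces the rotation exactly.

Movements whose sagittal excursion passes 90° (vertical flexion reaches
~157°) fold in a naive decomposition (x and y jump by 180°, z reflects).
`euler_unwrap()` re-selects, sample by sample, the algebraic solution
closest to a constant-velocity prediction and unwraps modulo 360°,
yielding continuous channels through an exact gimbal crossing. A
trajectory that passes *near* gimbal without touching it — a large
sagittal movement seen through a tilted sensor — has no continuous
representation reaching beyond 90° at all: the principal branch folds
smoothly and the branches never meet. That geometric fact shaped the
simulator's misalignment model (below). The simulator itself generates
Euler channels directly and never needs to re-decompose.

## What the synthetic cohort emulates

The generator reproduces the study design it is meant to stress-test: a
24-subject cohort, nine movement conditions performed once each at a
self-selected pace, observed simultaneously by a 500 Hz optical reference
and a 147 Hz wearable.

**Trajectories.** Each trial is lead-in (1 s at the start pose), a smooth
outward phase, a terminal hold (0.5 s), a smooth reverse phase, and a tail
(0.5 s). The smooth phases follow a minimum-jerk profile
`s(τ) = 10τ³ − 15τ⁴ + 6τ⁵` (zero velocity and acceleration at both ends),
the standard model for instructed, self-paced reaching-type movement; a
raised-cosine shape is available as an alternative. The minimum-jerk peak
velocity is `1.875·A/T` for amplitude `A` and phase duration `T`.

**Amplitudes and pace.** Default per-movement amplitudes and
between-subject SDs equal the reference-system means ± SDs of the emulated
cohort (e.g. abduction 160.9° ± 10.9°); per-subject draws are truncated at
3 SD and floored at 0.5° so ranges stay positive. Phase durations are set
so the minimum-jerk peak velocity matches the reference cohort's peak
angular velocity where one was reported (abduction: 1.875 × 160.9 / 90.5 ≈
3.3 s), with a comfortable 1.4 s chosen for the rotations, where no peak
velocity is reported, and 3.0 s for the multiplanar pattern. Each subject
additionally gets a movement-specific pace multiplier (SD 0.15, truncated
to [0.6, 1.5]) — without it every subject would have identical velocities
and velocity ICCs would be degenerate.

**The PNF pattern** starts away from neutral (vertical flexion / adduction
/ internal rotation: z = +143.8°, x = −50.1°, y = −14.4°) and ends on the
opposite side of all three channels (z = −27.3°, x = +19.2°, y = +55.8°).
Its per-channel outcomes are the start-pose and end-pose excursions from
neutral, whose sum is the channel's total arc.

**Error models.** Measurement error is injected at the angle level, per
system:

| mechanism | parameter | what it emulates |
|---|---|---|
| static offset (°/channel) | `static_offset_deg` | calibration-pose error |
| fixed frame rotation (°) | `misalignment_deg` | sensor tilt/rotation on the skin |
| per-channel gain | `amplitude_scale` | soft-tissue artifact attenuating or inflating excursions |
| random walk (°·s^−1/2^) | `drift_rate_deg_s` | accumulated sensor error, slow magnetic disturbance |
| white noise (°) | `noise_sd_deg` | residual measurement noise |

Soft-tissue artifact is modeled as gain + misalignment rather than a
biomechanical skin model, and magnetic disturbance is not modeled
separately from drift: at the angle level the two are indistinguishable.
These are deliberate simplifications — the mechanisms are only discussed
qualitatively in the validation literature, and the agreement statistics
see their combined angle-level effect anyway.

Misalignment deserves one more sentence. The physical cause is a fixed
rotation of the sensor frame, but composing that rotation with the true
orientation and re-decomposing would fold the XZ′Y″ representation of any
sagittal excursion beyond 90° (the near-gimbal passage described above),
collapsing vertical-flexion outcomes in a way no pipeline that reports
those movements can have exhibited. The misalignment is therefore applied
as its small-angle equivalent: the misalignment rotation acting on the
angle vector, i.e. deterministic cross-talk that leaks a sine-fraction of
each movement into the other channels and slightly attenuates the active
one. For the few-degree tilts this mechanism represents, the two
formulations agree to first order away from the degeneracy. The wearable's gyroscope
velocity channels are modeled as finite differences of the distorted
angles *before* the white-noise term: gyroscope noise is orders of
magnitude below angle noise at these rates, and differentiating the noisy
angles instead would swamp the velocity outcomes with artificial noise.
The reference stream carries no velocity channels; they are computed after
resampling.

Defaults: `reference_model()` is 500 Hz with 0.02° noise and nothing else;
`wearable_model()` is 147 Hz with 2° offsets, 2° misalignment components,
gain 0.95, drift 0.05 °·s^−1/2^ and 0.5° noise — mild, plausible values
for a body-worn system. Scenario studies override exactly the mechanism
under test.

**What passing tests do not show.** The simulator's errors are stationary,
additive/multiplicative and movement-independent. Real soft-tissue
artifact is posture- and velocity-dependent, real magnetic disturbance is
episodic, and a real vendor's sensor-fusion algorithm can fail
nonlinearly (the emulated study reported corrupted trials). Recovery of
injected parameters therefore validates the *pipeline*, not any specific
sensor product.

## Preprocessing

Both streams are brought to a common 200 Hz timebase: the 500 Hz reference
is downsampled through a zero-phase 4th-order Butterworth low-pass
(default cutoff 50 Hz, capped below the target Nyquist) and the 147 Hz
wearable is linearly interpolated. Linear interpolation is adequate
because shoulder movement lives below ~10 Hz; the amplitude error of a
1 Hz, 50° sinusoid through the whole resampling chain is under 0.1%. No
smoothing beyond anti-aliasing is applied. `signal::filtfilt` starts from
zero state, so each channel is detrended through its endpoints before
filtering and the trend restored afterwards; otherwise channels with a
non-zero baseline (the PNF start pose) would acquire large edge
transients.

Synchronization maximizes the FFT cross-correlation of the dominant
channel's angular velocity (the dominant channel is the one with the
largest excursion), then crops both streams to the common window. Lags up
to ±2 s are recovered to within one sample. If the correlation peak is
below 0.2 — featureless streams — a warning is issued and zero lag
applied. How the emulated study aligned its exported data sheets is not
stated; cross-correlation is the assumption, and `sync = FALSE` disables
it.

Baseline angle offsets are removed per channel as the mean over the first
0.5 s (configurable); the operation is idempotent and leaves every
outcome invariant. For the PNF pattern offset removal is *skipped*: its
start pose is itself an excursion from neutral, so absolute calibrated
angles must be retained to read the start-pose component.

## Outcome extraction

**Segmentation.** The study fragmented trials by visual inspection of
angle–time plots; `segment_phases()` automates this with a standard
velocity threshold: onset is the first sample where |velocity| of the
active channel exceeds 5% of its peak sustained for ≥ 100 ms, the outward
phase ends when velocity falls back below threshold (sustained), the
reverse phase is found symmetrically, and the terminal dwell is the gap
between them. The sustain requirement rejects isolated noise crossings.
On noiseless minimum-jerk profiles every boundary lands within one sample
of the analytic threshold crossing for all nine movements. Both streams
of one synchronized trial share the reference stream's phases: the
movement events are physically common, and per-stream fragmentation would
re-introduce one-sample window disagreements that contaminate the
velocity outcomes.

**ROM** is |terminal − baseline| on the active channel. Two windows make
this robust without biasing it:

* the *baseline* window ends a margin (10% of the outward-phase length)
  before the detected onset, because the threshold onset trails the true
  movement start and the sub-threshold early motion would otherwise leak
  into the baseline mean;
* the *terminal* value is the mean over the central part of the dwell,
  trimming 8% of the outward-phase length off each dwell edge. The dwell
  edges still belong to the smooth approach/departure (the velocity
  threshold cuts at 5% of peak, where the angle is ~0.2% short of
  end-range); the trimmed centre is the static hold, so the estimator is
  unbiased at end-range and averages additive noise instead of chasing
  noise peaks the way a pointwise extremum would. With no usable dwell it
  falls back to the full dwell mean, then to the signed extremum
  (earliest sample on ties).

**TROM** is the sum of the two opposing terminal ranges (e.g. the
external + internal rotation arc), computed per subject and system from
the two movements' ROM values; for PNF it is the within-trial sum of the
start- and end-pose excursions per channel.

**PAV** is the minimum and maximum of the velocity channel over outward ∪
reverse. By the emulated study's convention it is not reported for the
rotations or the PNF pattern (enforced, overridable). The agreement report
uses the peak magnitude `max(|min|, |max|)`.

**MAV** is the mean |velocity| over four narrow windows — the first and
last 25% (configurable) of each phase, i.e. just after initiation and just
before reaching the terminal/starting position. The study says only
"narrower time windows"; 25% is the documented default and is echoed in
the report metadata. Absolute velocity makes outward and reverse windows
comparable. For PNF, the windows adjacent to the start pose
(outward-early, reverse-late) and to the end pose (outward-late,
reverse-early) are averaged into "start" and "end" values per channel.

## Agreement statistics

Differences are **reference − test**, so a positive bias means the
wearable under-reads; this matches the sign of the published bias values
the package reconstructs. Limits of agreement use the sample SD (n − 1),
the standard Bland–Altman convention.

The ICC is the two-way mixed, single-measures coefficient computed from
the subjects × methods ANOVA mean squares. "Two-way mixed" does not pin
down consistency versus absolute agreement; the default is the consistency
form ICC(3,1) = (MS_R − MS_E)/(MS_R + (k−1)MS_E), which ignores a fixed
between-method offset, and the absolute-agreement form is available via
`form = "agreement"`. Both are tested against an independent `aov()`
oracle to 10⁻¹⁰. Interpretation bands are half-open: poor < 0.5 ≤
moderate < 0.7 ≤ good < 0.9 ≤ excellent (0.5 is "moderate", 0.9 is
"excellent").

RMSE is computed on the per-subject scalar outcome differences, so it
obeys `rmse² = bias² + (n−1)/n · var(d)` and in particular
`rmse ≥ |bias|`. Published method-comparison tables sometimes print RMSE
values smaller than |bias| for the same row, which is impossible under
this definition and indicates a different operand (time-series or demeaned
differences); the report therefore carries an explicit `rmse_ge_bias`
consistency flag.

Heteroscedasticity — conventionally judged by eye on the Bland–Altman
plot — is automated as the Kendall rank correlation between |difference|
and pair mean, with its p-value; rank-based because n = 24 is small and
differences need not be normal. The (mean, difference) pairs are returned
for plotting.

## Numerical and design notes

* Monte-Carlo problem sizes: the package's recovery studies use 200
  simulated 24-subject cohorts, LoA coverage uses 10⁵ differences, and
  oracle comparisons use 100–1000 random instances — sizes at which the
  Monte-Carlo error is well below the effects being measured while a full
  study run stays in the minutes range on one CPU.
* Determinism: every stochastic step takes a seed; per-trial sub-seeds are
  derived arithmetically (kept below 2³¹), so a full pipeline run is
  byte-for-byte reproducible, including the written files.
* Degenerate inputs are errors, not guesses: flat series cannot be
  segmented, zero total variance has no ICC, baseline windows longer than
  half the series are rejected, and trial files with NaN or non-monotone
  time report the offending line. In the pipeline a failing trial pair is
  dropped and logged (mirroring how corrupted field trials are handled)
  and the run continues.
* TROM pairing assumes the opposing movements of one arc are measured in
  the same subject and session, and pairs them subject-wise; published
  TROM means that are not the sum of the corresponding ROM means suggest
  other pairings exist, but subject-wise within-cohort pairing is the only
  one the data model supports.
* Known limitations: no confidence intervals for the ICC, no test–retest
  reliability (each condition is measured once, as in the emulated
  design), no marker-level or raw-sensor simulation, and no elbow
  kinematics for the PNF pattern.
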