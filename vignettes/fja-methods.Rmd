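---
title: "Quantifying fetlock joint angle patterns from paired inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fetlock joint angle patterns from paired inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fjagait)
```

## The measurement problem

The equine fetlock (metacarpo/metatarso-phalangeal) joint carries the largest
loads of any joint during locomotion, and the time course of its sagittal
angle — the fetlock joint angle pattern (FJAP) — is a sensitive indicator of
lameness. Two measurement routes exist:

* **Dual IMU**: one inertial sensor on the dorsal cannon bone
  (metacarpus/metatarsus) and one on the pastern, each reporting its
  orientation as a unit quaternion at 200 Hz plus triaxial angular velocity.
  The fetlock joint angle (FJA) is the relative rotation between the two
  sensors about the mediolateral axis.
* **Planar optical motion capture (OMC)**: three reflective markers at the
  carpus/tarsus, fetlock and coffin joint centers filmed at 60 Hz; the FJA is
  the dorsal angle between the pastern axis and the prolongation of the
  cannon axis.

`fjagait` implements both angle computations, the signal pipeline that makes
the two channels comparable, the agreement statistics between them, and a
synthetic gait generator that stands in for horse recordings so that every
stage is testable end to end.

The package's canonical angle convention is *flexion positive, extension
negative, zero at the standing calibration pose* (`apply_calibration()`
estimates the standing offset as the mean angle over a quiet standing
window of at least 0.5 s). The OMC dorsal-angle convention differs from the
IMU zero by a constant; the pipeline removes any constant offset during
y-axis alignment, so the two channels meet in a `common` frame.

## Angle extraction

**IMU.** For each sample the relative rotation is
`q_rel = conj(q_cannon) * q_pastern`; the signed sagittal angle is obtained
by swing–twist decomposition about the mediolateral axis, wrapped to
(−180°, 180°] and then unwrapped across samples (fetlock angles stay well
below 100°, so wrap events are unambiguous at 200 Hz). The computation is
exactly invariant to any common rigid rotation of both sensors, which is why
an idealized shared global reference frame (in the field established by a
calibration baseplate) is a sufficient model for simulation purposes.

**OMC.** Per frame, the cannon axis runs fetlock→proximal marker and the
pastern axis fetlock→distal marker; the angle is the signed planar angle
from the prolongation of the cannon axis to the pastern axis, with the sign
chosen so flexion increases it. Frames with coincident markers are flagged
and interpolated from neighbors; a trial with more than 10 % degenerate
frames is rejected.

## Signal pipeline

1. **Resampling**: the 60 Hz optical trace is brought to 200 Hz with a
   not-a-knot cubic interpolating spline (the construction used by MATLAB's
   `spline`, exact for cubic polynomials; implemented directly because no
   installed spline routine provides not-a-knot end conditions).
   Extrapolation beyond the recorded span is refused.
2. **Filtering**: both traces are low-pass filtered with a 4th-order
   Butterworth at 10 Hz, applied forward and backward so the filter is
   zero-phase (a causal filter would bias the synchronization step, which
   compares waveform timing). Edges are handled by odd-reflection padding
   with steady-state initial conditions; the pad length is three cutoff
   periods, which keeps the edge error of re-filtering a pass-band signal
   below 0.01°. A constant series passes through exactly (DC gain 1).
3. **Synchronization**: both signals are aligned at the point of absolute
   minimum between their first two local maxima. A maximum qualifies if its
   topographic prominence is at least 20 % of the trace's peak-to-peak range
   and it is separated from the previous qualifying maximum by at least
   0.2 stride durations (close peaks are merged, keeping the higher). These
   two thresholds reject noise wiggles while keeping the physiological
   double flexion peak distinct; both are exposed in `run_config()`.
4. **Vertical alignment**: the optical trace is shifted by the difference of
   the two signals at the synchronization point, so the traces agree exactly
   there.
5. **Stride segmentation**: stance is detected on the resultant (Euclidean
   norm) pastern angular velocity by hysteresis thresholding — enter stance
   below 8 % of the trial's robust maximum (98th percentile), leave above
   15 %, minimum stance duration 80 ms. Toe-on is the stance entry, toe-off
   the stance exit; a stride runs toe-on to toe-on. The reference literature
   for gyroscope-based event detection does not print its thresholds, so
   these three values are this package's reconstruction and are
   config-exposed.
6. **Range of motion**: per stride, `FJROM = |max(FJA) − min(FJA)|`; the
   reported value is the mean over the first three consecutive complete
   strides (`n_strides` in `run_config()`).

## Agreement statistics

For each limb-trial the aligned traces are compared by RMSE
(`sqrt(mean((x − y)^2))`), Pearson correlation with a two-sided p-value,
a Granger temporal-agreement test, and Bland–Altman bias and 95 % limits of
agreement.

**Granger test.** Both series are first-differenced; the lag order is chosen
by BIC over the unrestricted regression (own plus cross lags, up to 20
samples = 100 ms at 200 Hz), and an F test compares the restricted and
unrestricted models in each direction at α = 0.01. Selecting the order on
the unrestricted model is essential for power when the cross-dependence sits
at a lag the target's own autocorrelation does not reveal; the test remains
calibrated (type-I error compatible with 1 % over 1000 null replicates in
the package's own simulations). The direction of "temporal agreement" is
ambiguous in the field's usage, so both directions are reported and the
default verdict is agreement when *either* direction rejects; the rule is
switchable to *both*.

**Bland–Altman with repeated measures.** Each limb-trial contributes many
paired samples, so pooled limits computed across all pairs would ignore the
clustering. The `rm_corrected` method decomposes the difference variance by
a one-way analysis over subjects: total variance = within-subject mean
square + between-subject variance component (from the subject-means mean
square, with the unequal-replicate divisor `n0`); the limits are
`bias ± 1.96 × sqrt(total variance)`. Subjects with fewer than two pairs
trigger a pooled fallback with a warning.

**Variability analysis.** The left-right FJROM coefficient of variation
(`CV% = sd/mean × 100`, sample SD) is computed per horse, gait and lateral
pair — both pairs for sound horses, only the lame limb and its contralateral
for lame horses. The assembled table feeds a main-effects three-way ANOVA on
lameness, gait and limb pair (no horse-level term, matching the study design
this package reproduces), with a Shapiro–Wilk check on residuals that warns
rather than stops. Sums of squares are Type II (equal to Type I on balanced
designs); each factor's share of variation is reported as
`SS_factor / SS_total × 100`, the "percent of total variation" convention.
Interactions are not modeled because the analysis being reproduced reports
main effects only.

## The synthetic gait generator

No public recordings of the instrumented horses exist, so the generator
emulates the statistical structure the analysis assumes.

**Waveform.** One stride of FJA is a sum of wrapped Gaussian bumps on the
phase circle (phase 0 = toe-on): flexion peaks positive, extension peaks
negative. Walk alternates two flexion and two extension peaks; trot has a
double flexion peak in swing separated by a positive dip and a single
extension peak in stance. The template is rescaled so its exact continuous
range equals the requested ROM, and `flexion_peak_ratio` (default 0.9)
sets the height of the first flexion peak relative to the second. Bump
widths are chosen so the template is effectively band-limited below ~7 Hz at
the default stride durations — inside the 10 Hz filter pass-band — which
keeps the zero-noise pipeline round-trip error of the planted ROM below
0.3°. "Flexion peaks" are counted as strict local maxima with positive
value and "extension peaks" as strict local minima with negative value;
the dip between the trot flexion peaks is a strict minimum but, being
positive, not an extension peak.

**Kinematic chain.** The pastern's absolute sagittal angle is quiet during
stance (the hoof is planted) and carries two opposite rotation lobes
spanning swing; the cannon angle is defined as pastern − FJA, closing the
chain so the relative sensor rotation reproduces the planted angle exactly.
The swing lobes sit at 24 % and 76 % of swing with widths of 13 % and 12 %
of swing, placing the sustained low-angular-velocity interval within ~2 % of
the planted stance window, so gyroscope-based segmentation can be validated
against ground truth. Records span stride phases −0.33 to `n_strides` +
0.17: they begin mid-swing away from any waveform extremum (an extremum
within ~15 samples of a record edge has edge-truncated prominence and makes
peak detection unstable) and contain exactly `n_strides` complete strides.

**Footfalls.** Walk uses the four-beat lateral sequence (LH, LF, RH, RF at
quarter-stride offsets); trot uses synchronous diagonal pairs half a stride
apart.

**Noise model.** IMU: white gyroscope noise (default 1°/s per axis) and
small random orientation perturbations of each sensor (default 0.3°). OMC:
white digitization noise of 1.0 mm per marker coordinate — about 0.2 px at
the ~5 mm/px field of view the emulated video setup implies, the precision
of automatic centroid tracking of 40 mm retroreflective markers — plus a
2 mm soft-tissue marker displacement modeled as correlated noise
band-limited below ~1.5 Hz, near the stride frequency where skin-slide
artifact lives. These defaults were fixed together with the design
requirement that waveform synchronization recover planted lags to ±2
samples; coarser manual digitization (several mm of white noise) degrades
the synchronization minimum and the agreement statistics roughly in
proportion.

**Cohort structure.** Per-horse sound ROMs are drawn around front/hind ×
walk/trot population means (57.79/60.48° at walk, 82.83/89.40° at trot, with
between-horse SDs of 4.5–6.6°). Left-right asymmetry is parameterized by the
expected pair CV (3.00/2.51 % front, 3.91/3.60 % hind at walk/trot): for two
sides with independent `N(0, σ)` relative deviations,
`E[CV%] = 100·σ·sqrt(2/π)`, so `σ = CV/100·sqrt(π/2)`. Each lame horse gets
one uniformly drawn lame limb whose waveform is scaled by a per-horse
lameness factor; the factor means derive from the expected
lame-vs-contralateral CV (15.47 % walk, 7.06 % trot) through
`CV% = 100·sqrt(2)·(1−f)/(1+f)`, giving 0.80 at walk and 0.90 at trot,
jittered with SD 0.03 and clamped to [0.5, 0.98]. Speeds are 1.53 m/s
(walk) and 3.56 m/s (trot); stride lengths 2.5 m at trot and 1.8 m at walk
(the walk value is a package choice — a plausible ~1.2 s walk stride — as
the emulated study reports none).

## What the simulations do and do not show

The generator produces planar, strictly periodic kinematics with stationary
Gaussian sensor noise and an exactly shared time base. It does not emulate
stride-to-stride timing variability, out-of-sagittal-plane motion,
perspective or lens distortion, marker occlusion, orientation drift, or the
breed and conformation heterogeneity of real cohorts. Passing tests
therefore demonstrate that the pipeline and statistics are implemented
correctly and recover planted structure under realistic noise — not that
the method achieves any particular accuracy on real horses. Simulated RMSE
(~3°) is accordingly lower than values reported from field data (~8–10°),
where soft-tissue artifact and camera geometry dominate.

## Numerical choices and degenerate inputs

* Not-a-knot spline: the tridiagonal-plus-corner system in the knot second
  derivatives is solved sparsely; evaluation refuses extrapolation.
* Filter: odd-reflection padding of three cutoff periods with steady-state
  initialization; series shorter than three pad lengths are rejected.
* Peak prominence: computed topographically (walk to the nearest higher
  value on each side, take the higher of the two interval minima).
* Stride segmentation: a leading low-velocity interval whose entry was not
  observed is discarded; a trailing stance without an observed exit
  contributes a toe-on only. A trial whose robust maximum resultant velocity
  is below 10°/s is rejected as motionless.
* `cv_percent` rejects a zero mean; `pcc` rejects zero variance; Granger
  rejects constant series and series shorter than 10 × `max_lag`.
* All-equal ANOVA responses return zero sums of squares and percents with
  `NA` test statistics rather than dividing by zero.
* Ties in `which.min`/`which.max` resolve to the earliest sample, making
  synchronization deterministic.

## Known limitations

* At walk, the broad extension trough combined with the low-frequency
  soft-tissue artifact leaves a small tail (≲0.5 % of trials at default
  noise) of synchronization minima displaced by ±3 samples (15 ms); the
  effect on RMSE/PCC is minor but visible in single trials.
* The Granger "agreement" verdict with the `either` rule is permissive by
  construction; for near-identical traces both directions reject anyway.
* The repeated-measures Bland–Altman variant implements a components-of-
  variance correction; other repeated-measures formulations exist and can
  give slightly different limits when subjects are strongly unbalanced.

## Study drivers

`run_validation_study()` mirrors a method-validation layout: per limb-trial
RMSE/PCC/Granger, aggregated by gait and group, plus Bland–Altman over
pooled samples (subjects = limb-trials) and over FJROM (subjects = horses).
`run_variability_study()` assembles the CV table and ANOVA partition.
`run_demo_study(n_sound = 7, n_lame = 7, seed)` runs both on a freshly
simulated cohort of 14 horses at both gaits — the configuration
`scripts/acceptance.R` executes. At these problem sizes (five strides per
record, 112 limb-trials) the full demonstration completes in a few seconds.
Every report embeds the fully resolved `run_config()` and the cohort seed.
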