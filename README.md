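# fjagait

Quantification of the equine sagittal **fetlock joint angle** (FJA) pattern
and its per-stride **range of motion** (FJROM) from two wearable inertial
sensors per limb, with agreement analysis against planar optical motion
capture (OMC) and a variability analysis of left–right FJROM asymmetry in
sound and lame horses.

The fetlock (metacarpo/metatarso-phalangeal) joint experiences the largest
loads in the equine limb, and changes in its angle pattern are a sensitive
indicator of lameness. Two inertial sensors — one on the dorsal cannon bone,
one on the pastern, each reporting a unit-quaternion orientation at 200 Hz —
measure the joint angle as the relative rotation about the mediolateral
axis:

    q_rel(t) = conj(q_cannon(t)) ⊗ q_pastern(t),   FJA(t) = twist_z(q_rel(t))

with flexion positive, extension negative and zero at the standing
calibration pose. The optical channel computes, per 60 Hz video frame, the
dorsal angle between the pastern axis (fetlock → coffin marker) and the
prolongation of the cannon axis (fetlock → carpus/tarsus marker). The
processing pipeline brings both traces to 200 Hz (not-a-knot cubic spline),
low-pass filters them (4th-order zero-phase Butterworth, 10 Hz cutoff),
synchronizes them at the absolute minimum between the first two prominent
maxima, aligns them vertically at that point, segments strides from the
resultant pastern angular velocity (hysteresis stance detection), and
computes

    FJROM_stride = | max(FJA_stride) − min(FJA_stride) |

averaged over three consecutive strides. Agreement between the channels is
reported as RMSE, Pearson correlation, a Granger temporal-agreement test
(α = 0.01, BIC-selected lag ≤ 100 ms, both directions), and Bland–Altman
bias and 95 % limits of agreement with a repeated-measures correction.
Left–right FJROM variability (CV % = sd/mean × 100) feeds a three-way
main-effects ANOVA on lameness, gait and limb pair, with each factor's
share of variation reported as SS_factor/SS_total × 100.

Because no public recordings exist for this instrumentation, the package
includes a first-class synthetic gait generator (walk and trot waveform
morphology, four-limb footfall phasing, configurable lameness, gyroscope /
orientation / marker digitization / soft-tissue noise, both sampling rates)
so that the entire pipeline is testable end to end against planted ground
truth. See the methods vignette (`vignettes/fja-methods.Rmd`) for the model
and all numerical choices.

## Worked example

Simulate one trotting limb with a planted 83° range of motion, run both
measurement channels through the pipeline, and compare them:

```r
library(fjagait)

p   <- gait_params("trot", rom_deg = 83)
rec <- simulate_limb(p, limb_id = "LF", phase_offset = 0, seed = 7)
res <- analyze_limb_pair(rec)

res$fjrom_imu
#> <fjrom_summary> mean ROM 82.78 deg over 3 strides (per-stride: 82.64, 82.87, 82.85, 82.82, 82.67)
res$agreement
#> <fja_agreement> n = 771 samples
#>   RMSE 2.55 deg | PCC 0.9964 (p = 0)
#>   Granger agree: TRUE (p_fwd 2.58e-40, p_rev 0.0031)
#>   Bland-Altman bias -1.166 deg, LoA [-5.62, 3.29]
```

The IMU channel recovers the planted 83° ROM to 0.2° (the residual is the
10 Hz filter's slight rounding of the flexion peaks); the RMSE of ~2.5°
against the optical channel reflects the default marker digitization and
soft-tissue noise.

A full study — 7 sound and 7 lame horses, four limbs each, walk and trot —
runs in a few seconds:

```r
demo <- run_demo_study(n_sound = 7, n_lame = 7, seed = 42)
demo$validation
#> <fja_validation_study> 112 limb-trials (0 excluded)
#>   trot  RMSE 2.97 +/- 0.85 deg | PCC 0.997 +/- 0.001 | Granger agree 100.0%
#>   walk  RMSE 2.83 +/- 1.09 deg | PCC 0.992 +/- 0.003 | Granger agree 100.0%
#>   overall Granger temporal agreement: 100.00% of limb-trials
demo$variability
#> <fja_variability_study> 42 left-right CV records (0 excluded)
#>   mean CV lame  trot    7.97%
#>   mean CV lame  walk   15.36%
#>   mean CV sound trot    4.09%
#>   mean CV sound walk    3.88%
#> <anova_partition> main-effects ANOVA of left-right ROM CV
#>   lameness   SS   476.33  F   28.98  p  3.99e-06  % of total  37.74
#>   gait       SS    56.85  F    3.46  p    0.0707  % of total   4.50
#>   limb_pair  SS    30.74  F    1.87  p      0.18  % of total   2.44
#>   residual   SS   624.66                         % of total  49.49
#>   Shapiro-Wilk residual normality p = 0.589
```

Sound horses show low (< 5 %) left–right CV at both gaits; lame horses show
markedly higher asymmetry, and lameness is by far the largest source of
left–right FJROM variation — the qualitative structure such a study is
designed to detect.

A thin command-line front end with `simulate`, `validate`, `report`,
`variability` and `demo` subcommands is installed at
`inst/cli/fjagait.R`; all outputs are CSV/JSON with the fully resolved
configuration embedded for provenance.

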