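Package: fjagait
Title: Equine Fetlock Joint Angle and Range of Motion from Paired Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the equine sagittal fetlock joint angle (FJA) pattern and
    its range of motion (FJROM) from two inertial measurement units per limb
    (cannon and pastern orientation quaternions plus pastern gyroscope), and
    assesses agreement against planar optical motion capture. Includes a
    synthetic gait generator for walk and trot with configurable lameness,
    sensor noise and soft-tissue marker artifact; a signal pipeline with
    not-a-knot cubic spline resampling, zero-phase Butterworth low-pass
    filtering, waveform synchronization, gyroscope-based stride segmentation
    and per-stride range-of-motion extraction; and agreement statistics
    (RMSE, Pearson correlation, Granger temporal-agreement testing,
    Bland-Altman limits of agreement with repeated-measures correction,
    left-right coefficient of variation, and a three-way ANOVA partition of
    range-of-motion variability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    car,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
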