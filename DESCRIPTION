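Package: wristpa
Title: Physical Activity Endpoints from Raw Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes raw tri-axial wrist accelerometer recordings into
    daily physical activity endpoints. Implements unit-sphere
    autocalibration, non-wear detection from acceleration variance and
    near-body temperature, heuristic sleep-window estimation from wrist
    angle variability, wear-gated per-day computation of windowed Euclidean
    Norm Minus One (ENMO), cut-point time-in-level and bout endpoints, the
    intensity gradient, bout-accumulation (fragmentation) metrics, and a
    statistical layer for method comparison (ICC, repeated-measures
    correlation, mixed-effects mean differences) and two-group age-effect
    analysis. Includes a semi-Markov free-living simulator that produces
    multi-day recordings with ground-truth wear, sleep, activity-state and
    calibration labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
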