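Package: rootwave
Title: Quantification of Calcium Wave Kinematics in Root Fluorescence Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify bi-directional calcium-signal propagation in
    plant primary roots imaged on dual-flow microfluidic chips. Builds
    kymographs from time-lapse fluorescence stacks by transverse or
    longitudinal summation inside a region of interest, extracts intensity
    traces at five standard linear sections along the root axis, detects
    wave fronts by half-maximum crossing, estimates signed propagation speed
    with a robust Theil-Sen fit, classifies direction (shoot-ward, tip-ward,
    bidirectional), computes fold changes, and compares conditions by two-way
    ANOVA with Tukey HSD. Includes a synthetic-video generator that renders a
    root phantom with a propagating fluorescence front, realistic shot and
    read noise and optical blur, paired with machine-readable ground truth,
    so estimator accuracy can be validated by parameter recovery. A
    closed-form microfluidic transit model relates channel flow speed to the
    much slower tissue-borne signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    readr,
    jsonlite,
    tiff,
    EBImage,
    generics,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
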