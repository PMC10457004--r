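Package: mfeitsym
Title: Multifrequency EIT Brain-Asymmetry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multifrequency electrical
    impedance tomography (MFEIT) of the head. Provides a deterministic 2D
    finite-element forward model on a circular 16-electrode domain, a
    synthetic-data generator for healthy (left-right symmetric) and
    unilaterally lesioned head phantoms with frequency-dependent tissue
    conductivities, resistor-network calibration, frequency-difference image
    reconstruction by damped least squares with standard Tikhonov
    regularization, effective region-of-interest extraction, per-side area and
    signal-intensity features, the geometric (GAI) and intensity (IAI)
    asymmetry indices, positive-event rate analysis, and nonparametric
    (Wilcoxon rank-sum) group comparisons between healthy and diseased
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
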