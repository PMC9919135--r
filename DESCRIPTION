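Package: enoseflow
Title: Flow Correction for Active-Pumping Electronic-Nose Trace-Gas Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration pipeline for ppb-level nitric-oxide detection with an
    active-pumping electronic nose whose sensor response depends on the pump
    suction flow. Provides a synthetic two-channel run simulator emulating a
    factorial concentration-by-flow bench experiment, smoothing and five-feature
    extraction (maximum, mean, median, Q1, Q3), balanced two-factor ANOVA with
    interaction and LSD homogeneous subsets, quadratic multivariate-regression
    calibration, a genetic-algorithm-initialized backpropagation network, and a
    threshold-switched hybrid of the two calibrators, with full-scale precision
    metrics and an end-to-end reproducible pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
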