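Package: hmrconv
Title: Collimator-Aware Standardization of the I-123 MIBG Heart-to-Mediastinum Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and machine-learning pipeline for
    standardizing the heart-to-mediastinum count ratio (HMR) of planar
    I-123 MIBG scintigraphy across gamma-camera collimators.  Builds a
    digital three-layer calibration phantom, projects it through an
    analytic multi-energy camera model with collimator septal
    penetration and Poisson noise, computes phantom conversion
    coefficients, and trains a gradient-boosted regression that predicts
    conversion coefficients directly from collimator hole diameter,
    septal thickness and length.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
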