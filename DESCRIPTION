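Package: cropsens
Title: Global Sensitivity Analysis and Evaluation Tools for Crop Growth Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-based global sensitivity analysis of crop growth model
    parameters with the extended Fourier Amplitude Sensitivity Test (EFAST),
    including search-curve sampling, first-order and total-order Sobol
    indices, and a Monte-Carlo pick-freeze cross-check. Ranking stability
    across sites and years is quantified with savage scores and the top-down
    concordance coefficient with a chi-squared significance test. Model
    calibration and evaluation statistics (RMSE, nRMSE, mean error, relative
    mean error, Willmott's index of agreement) are computed from paired
    observed and simulated season outcomes. Daily weather inputs can be
    synthesised from seasonal summaries or read from CSV and DSSAT-style
    weather files, with solar radiation estimated from sunshine hours by the
    Angstrom-Prescott equation. A self-contained daily rapeseed growth
    surrogate with the cultivar, ecotype and soil parameter interface of
    CROPGRO-Canola makes the full analysis pipeline executable without an
    external simulator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
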