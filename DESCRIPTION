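Package: retrep
Title: Repeatability and Robustness Analysis for Retinal Trait Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying test-retest repeatability of image-derived
    retinal traits such as vessel fractal dimension. Implements
    population-level metrics (paired correlations, random-pair resampling
    with empirical confidence intervals, intraclass correlation from a
    between-/within-eye variance decomposition), the individual-level
    relative-noise statistic lambda, image-quality exclusion sweeps,
    lambda-versus-quality correlation on probability and logit scales,
    between-method interchangeability with Bland-Altman summaries, and a
    synthetic cohort generator with known ground truth for validating the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
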