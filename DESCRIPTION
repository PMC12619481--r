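Package: ebmcascade
Title: Event-Based Modelling of Cognitive and Gray-Matter Decline with
    Principal-Component Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-sectional disease-progression analysis for cohorts of
    patients and healthy controls: reduces item-level neuropsychological
    batteries (CVLT, STROOP, WCST) to principal components with
    Kaiser-Meyer-Olkin and Bartlett adequacy checks, fits per-biomarker
    normal/abnormal Gaussian mixtures, estimates the temporal ordering of
    biomarker abnormality events by minimising total probabilistic
    Kendall-tau distance, places event-centers on a [0,1] timeline, stages
    subjects by expectation-maximisation over a stage prior, quantifies
    ordering uncertainty with bootstrap positional-variance matrices, and
    runs the downstream covariate-adjusted group and partial-correlation
    statistics with Benjamini-Hochberg control. Ships a synthetic-cohort
    generator with known ground-truth event sequence so every stage is
    testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
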