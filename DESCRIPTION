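Package: itrlearn
Title: Individualized Treatment Rules for Multi-Arm Observational Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and honest evaluation of individualized treatment
    rules (ITRs) for choosing among many treatment arms from observational
    cohort data. Implements a cross-validated stacking ensemble (Super
    Learner) with convex weights chosen by non-negative least squares,
    doubly robust (AIPW) patient-level difference scores contrasting each
    arm with the observed population, second-stage per-arm regressions
    whose argmax defines the rule, targeted minimum loss-based estimation
    (TMLE) of the mean outcome under any deterministic or stochastic
    allocation scheme with influence-curve standard errors, permutation
    variable importance for prescriptive predictors, and a seeded
    synthetic claims-like cohort generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    glmnet,
    ranger,
    mgcv,
    caret,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
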