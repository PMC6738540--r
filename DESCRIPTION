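Package: growthspurt
Title: Shape-Invariant (SITAR) Modelling of Adolescent Height Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the adolescent growth spurt in longitudinal
    cohorts: LMS-based z-score conversion against age-indexed growth
    references with WHO stunting and BMI categories; a shape-invariant
    (SITAR) nonlinear mixed-effects growth model with a natural cubic
    spline mean curve, per-subject size, timing and intensity random
    effects and covariate fixed effects on their means, fitted by
    iterated linearization; growth-velocity curves and age at peak
    height velocity; cohort-construction rules (eligibility, censoring,
    baseline anthropometry, implausible-measurement checks); a
    second-stage regression of subject-level growth parameters on
    clinical covariates; and a synthetic-cohort generator with exported
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    splines,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
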