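Package: bmicorrect
Title: Statistical Correction of Self-Report Bias in Adolescent Height and
    Weight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing self-report bias in adolescent height and
    weight from survey cohorts. Implements linear correction equations
    predicting measured height and weight from self-reported values and
    biopsychosocial covariates (including a bundled published coefficient
    set), BMI-for-age weight-status classification via the LMS growth-chart
    method with adult cutoffs, probability-weighted least-squares refitting
    with block-wise AIC model selection and two-way interaction screening,
    and evaluation of correction quality through weighted correlations,
    sensitivity/specificity diagnostics with Wilson or Clopper-Pearson
    confidence intervals, and 4x4 weight-status misclassification
    contingency tables with over/under-estimation decomposition. A
    synthetic-cohort generator emulates measured anthropometrics,
    status-dependent self-report bias, and correlated covariates so the
    full pipeline is testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
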