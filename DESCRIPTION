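Package: equityaudit
Title: Auditing Demographic Inequalities in Early-Psychosis Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for monitoring inequalities in symptomatic outcomes across
    demographic groups in early-intervention-in-psychosis audit data. Provides
    a patient-level cohort data model with exclusion tracking and chi-squared
    balance checks, observational mean-outcome-change summaries with bootstrap
    confidence intervals, a leave-one-covariate-out nearest-neighbour matching
    estimator of the moderation effect of demographic category membership
    (with bootstrap re-matching confidence intervals), and an ordinal probit
    regression of outcome-change categories with demographic-by-treatment
    interaction terms. A seeded synthetic cohort generator with known
    ground-truth effects supports calibration and power studies without access
    to restricted audit data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
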