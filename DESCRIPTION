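Package: gompertzSM
Title: Gompertz Survival Modelling with Strehler-Mildvan Artifact Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Parametric survival analysis of rodent lifespan cohorts with the
    Gompertz mortality model: maximum-likelihood and curve least-squares
    estimation of the initial mortality and the rate of aging with Wald 95%
    confidence intervals; construction of the artifactual Strehler-Mildvan
    reference regression of ln(mu0) on gamma by subsample refitting; and
    classification of parameter-change vectors between cohorts as real
    aging-rate changes, real initial-mortality changes, or largely artifactual
    displacements. Also provides tumor-censored Kaplan-Meier comparison with
    log-rank tests, cohort summary statistics, contingency and rank tests, and
    seeded synthetic-data generators (two-strain Gompertz cohorts with
    age-dependent tumor labels, digitized-style survival-curve points, and
    cross-sectional organ panels with declining thymus and thymulin
    trajectories) so that every pipeline stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    minpack.lm,
    pracma,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    optparse
Config/testthat/edition: 3
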