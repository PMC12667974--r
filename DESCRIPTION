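Package: gngbias
Title: Pavlovian Bias in the Orthogonalized Go/No-Go Task and Smoking
    Cessation Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian estimation of a
    Rescorla-Wagner reinforcement-learning model with go bias, valence-specific
    Pavlovian bias, outcome sensitivity and irreducible noise on the
    orthogonalized go/no-go task. Supports two-session designs with additive
    session-change (delta) parameters, non-centered hierarchical MCMC
    estimation with split R-hat diagnostics and highest-density-interval
    summaries, behavioral congruency contrasts with pooled-SD effect sizes,
    cohort quality-control filters, CO-verified abstinence classification, and
    a logistic moderation analysis linking Pavlovian bias and clinic
    participation to cessation success. Includes a synthetic-cohort generator
    with known ground truth for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
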