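Package: ipdpool
Title: Two-Stage Pooled Analysis of Multisite Randomized Trials with a
    Binary Outcome
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-participant-data analysis of multisite randomized
    trials with a binary endpoint: covariate-adjusted logistic treatment
    effects fitted per study (with Firth penalization under separation),
    inverse-variance fixed-effect pooling of the study log-odds ratios,
    a within-study permutation test of the pooled effect, a stratified
    bootstrap percentile confidence interval, and a Bayesian hierarchical
    logistic model as a sensitivity analysis.  Includes a synthetic
    multi-site trial generator (per-study designs, covariates, missingness
    and post-randomization exclusion processes), CONSORT-style exclusion
    filters, worst-case missing-as-positive imputation, baseline-table
    summaries, and operating-characteristics simulations (type-I error,
    coverage, power, parameter recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
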