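Package: antiseq
Title: Sequential Dependence in Antisaccade Task Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing trial-history effects in the antisaccade
    task across clinical cohorts (Alzheimer's disease, mild cognitive
    impairment, controls). Provides a seeded synthetic-cohort generator with
    a rise-to-threshold (race) reaction-time model and raw gaze traces, a
    saccade classifier (spike filtering, velocity/acceleration event
    detection, outcome and correction labelling), previous-outcome and
    run-length conditioning statistics with log-odds ratio and Wald tests,
    a Bernoulli random-intercept multilevel model fitted by adaptive
    Gauss-Hermite quadrature with parametric-bootstrap confidence intervals,
    and Kaplan-Meier reaction-time survival summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
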