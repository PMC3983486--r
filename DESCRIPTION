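Package: conformity
Title: Simulation and Analysis of Social Feedback Updating Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying social conformity as belief updating toward
    peer feedback on character traits. Provides a generator for the
    trait-feedback paradigm (stimulus sets, run schedules, and a feedback
    engine that manipulates feedback discrepancies on a fixed rating grid), a
    synthetic-cohort simulator with per-participant update fractions linked to
    self-construal covariates, trial classification and scoring (reverse
    coding, feedback desirability, relative mean updates, feedback-memory
    errors), and the matching inference layer: split-plot factorial ANOVA with
    partial eta-squared, Pearson correlations with Fisher-z confidence
    intervals, tests comparing independent and dependent correlations, and
    hierarchical-regression F-change tests. Includes parameter-recovery
    utilities that validate the scoring pipeline against known simulated
    update fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
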