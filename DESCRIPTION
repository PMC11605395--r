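Package: rilpk
Title: Population Pharmacokinetics of Oral and Long-Acting Injectable Rilpivirine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-compartment population pharmacokinetic model for rilpivirine
    given orally (zero-order absorption) and as a long-acting intramuscular
    nanosuspension (parallel fast/slow first-order depot absorption with
    flip-flop kinetics). Provides closed-form and ODE concentration profiles,
    a hierarchical between-subject/inter-occasion variability layer, synthetic
    cohort generation emulating a sparse routine-care sampling design,
    Laplace-approximation mixed-effects estimation with stepwise covariate
    selection and bootstrap, Monte-Carlo trough-concentration and
    threshold-attainment simulation, and model qualification via
    prediction-corrected visual predictive checks and cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
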