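Package: txapopk
Title: Population Pharmacokinetics of Intravenous Tranexamic Acid in
    Obstetric Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic analysis of intravenous tranexamic
    acid given during hemorrhagic caesarean delivery. Provides event-record
    datasets mixing timed plasma concentrations and interval urine
    collections, candidate compartmental models with a urinary excretion
    fraction, nonlinear mixed-effects estimation by stochastic approximation
    EM (SAEM) with MCMC conditional sampling, covariate forward selection
    under corrected-BIC, condition-number and Wald criteria, simulation-based
    diagnostics (visual predictive checks, normalized prediction distribution
    errors, case bootstrap), noncompartmental analysis, Monte Carlo dose
    simulation over a virtual parturient population, and a synthetic trial
    generator emulating a two-arm caesarean-delivery design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
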