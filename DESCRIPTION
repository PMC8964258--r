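Package: probswitch
Title: Simulation, Modeling and Trait Analysis for Probabilistic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-choice probabilistic switching (reversal learning)
    task: a task engine with pre-randomized outcome schedules and uniform switch
    criteria; generative choice agents (Q-learning with counterfactual updating
    and sticky choice, and a Bayesian latent-state inference model); hierarchical
    Bayesian parameter estimation by MCMC with convergence diagnostics, WAIC model
    comparison and generate-and-recover harnesses; model-free behavioral
    statistics (switch-aligned accuracy, one- and three-back stay probabilities,
    action-conditioned two-back analysis); S-UPPS-P impulsivity questionnaire
    scoring with normality-gated correlations and mixed-effects trial-history
    regressions; and a synthetic-cohort generator with planted trait-behavior
    correlations for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
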