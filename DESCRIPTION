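Package: mimicrl
Title: Reinforcement Learning and Drift Diffusion Modelling of Facial
    Expression Avoidance Learning
Version: 0.1.0
Authors@R:
    person("Mimicrl", "Developers", email = "mimicrl@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for dyadic facial-expression
    avoidance-learning experiments in which participants learn by
    trial-and-error to reciprocate or oppose the smile or frown of two
    target interactants, with a mid-experiment contingency reversal.
    Provides balanced randomized trial schedules, trial-level scoring and
    exclusion rules, a family of Rescorla-Wagner Q-learning models over
    copy/not-copy actions with a static copy bias, a response-coded
    hierarchical Wiener drift diffusion model, hierarchical Bayesian
    fitting by MCMC, PSIS-LOO model comparison, posterior-predictive
    learning curves, posterior contrasts, and a ground-truthed synthetic
    data generator for parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
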