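Package: threestage
Title: Simulation and Model-Based/Model-Free Analysis of a Three-Stage
    Markov Decision Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a two-choice, three-stage Markov decision task with
    specific/flexible goal conditions and low/high state-transition
    uncertainty, and analyses trial-level choice data with model-free
    (SARSA) and model-based (forward transition learning plus backward
    goal-conditioned planning) reinforcement-learning models. Provides
    per-subject maximum-likelihood fitting with multi-restart Nelder-Mead,
    AIC/BIC model comparison, the derived arbitration measures (system
    preference and system switching), synthetic-cohort generation with
    known agent parameters for parameter-recovery studies, and the
    group-comparison layer (pooled t-tests, Benjamini-Hochberg FDR,
    Cohen's d, correlations, covariate-adjusted linear models).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
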