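Package: rlwm
Title: Reinforcement Learning and Working Memory Modelling of
    Instrumental Learning Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and maximum-likelihood estimation of the RLWM
    model, a mixture of a delta-rule reinforcement-learning system and a
    fast, capacity-limited, decaying working-memory system, for
    trial-level choice data from stimulus-action association tasks.
    Includes a task-schedule generator with pseudo-random interleaving,
    a trial-log CSV dialect, logistic growth-curve analysis of learning
    curves, a synthetic cohort generator with age- and cognitive-status
    structured parameters and reaction times, and the group comparison
    statistics (normality-gated two-sample tests, Spearman and regression
    age trends, ANOVA with Tukey HSD, a logistic age-cutoff classifier,
    inverse efficiency scores) used to analyse such cohorts.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
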