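Package: placeborl
Title: Placebo Treatment-Efficacy Expectations and Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of a probabilistic
    reinforcement learning task performed under graded expectations of sham
    treatment efficacy. Provides the task design (three stimulus pairs with
    80:20, 70:30 and 60:40 reward contingencies, 40 trials per pair), a
    synthetic-cohort generator with five efficacy groups and configurable
    inverted-U / monotonic / null group patterns, dual-rate Q-learning and
    extended (forgetting, irreducible-noise, choice-kernel) model variants,
    hierarchical posterior sampling with wide and narrow prior variants,
    posterior pattern statistics (monotonic and inverted-U fractions,
    pd/ps/ROPE contrasts, quadratic trend regression), model evaluation
    (model accuracy, posterior predictive simulation, PSIS-LOO, parameter
    recovery), and behavioral summaries (optimal choices, collected reward,
    stay probability, sliding-window correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    coda,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
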