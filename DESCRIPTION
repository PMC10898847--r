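Package: twosteprl
Title: Model-Based and Model-Free Analysis of the Two-Step Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, computational modelling and group-level statistics for
    the Two-Step sequential decision task. Provides the task environment
    (probabilistic 70/30 transitions, Gaussian random-walk reward
    probabilities), a hybrid model-based/model-free Q-learning agent with a
    repetition bias and shared learning/forgetting rate, hierarchical
    empirical-Bayes maximum a posteriori fitting with a chance-model
    likelihood-ratio screen, parameter-recovery simulation, quality-control
    filters for task disengagement, a two-group two-session synthetic cohort
    generator, and the stay/switch mixed logistic regressions, marginal-means
    post-hocs, rank-sum tests and mixed ANOVAs used to compare groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    emmeans,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
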