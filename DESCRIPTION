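Package: habitree
Title: Dual-System Reinforcement Learning with Bayesian Arbitration
Version: 0.1.0
Authors@R:
    person("habitree", "maintainers", email = "maintainers@habitree.dev",
           role = c("aut", "cre"))
Description: Simulates the competition between a model-free habitual
    controller (Beta posteriors over cached action values) and a model-based
    goal-directed controller (Dirichlet transition model with value
    iteration), arbitrated per action by the value of perfect information
    against the opportunity cost of deliberation, and extended with
    learning-progress intrinsic rewards and action-dependent transition
    costs. Ships two tabular tasks (a two-step feeder and a partially
    observable Playroom) and seeded experiment harnesses for outcome
    devaluation, activity, model acquisition, and promised-reward studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
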