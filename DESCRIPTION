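Package: carlbandit
Title: Collective Asymmetric Reinforcement Learning on Two-Armed Bandits
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of groups of Q-learning agents with
    asymmetric (confirmation-biased) learning rates solving a static
    two-armed Bernoulli bandit with payoffs in {+1, -1} under full mutual
    observation. Provides the collective asymmetric update rule, softmax
    action selection, a deterministic (expected-update) two-agent model
    for fixed-point and stability analysis, and an analysis suite for
    performance, final Q-value-gap distributions, kernel-density peak
    (regime) detection, bias-strength optimisation and polarization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
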