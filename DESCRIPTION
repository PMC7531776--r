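Package: foragefly
Title: Trial-Based Analysis of Probabilistic Reward Foraging in Walking Flies
Version: 0.1.0
Authors@R: person("Foraging", "Analysis", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-animal probabilistic reward foraging
    in linear-track arenas with closed-loop optogenetic stimulation.
    Provides synthetic session generation (virtual arena with a
    reset-then-reward trigger rule, and trial-level reinforcement-learning,
    deterministic and random agents), trajectory preprocessing and kinematic
    observables (stops, turns, occupancy, preference index, angular
    distribution entropy), trial segmentation into binary reward/return
    sequences, logistic-regression reward-history kernels, three
    reinforcement-learning models (Rescorla-Wagner, forgetting-Q, and
    forgetting-Q with a separate forgetting rate) with multistart maximum
    likelihood fitting, AIC model comparison, predictive F1 scoring and
    generative run-length testing, plus a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
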