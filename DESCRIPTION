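Package: vpvdrl
Title: Reinforcement Learning Models for Valence-Probe Visual Discrimination Reversal Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the valence-probe visual discrimination
    (VPVD) reversal-learning task used in rodent touchscreen studies of
    serotonergic modulation of cognitive flexibility. Provides the task
    schedule generator (standard A+/B- trials with embedded 50%-reinforced
    probe trials), a nine-member family of Q-learning models with split
    reward/punishment learning rates, softmax choice with stimulus and side
    stickiness, and trial-wise value forgetting; hierarchical Bayesian fitting
    by adaptive Markov chain Monte Carlo with an Rcpp likelihood kernel;
    Bayesian model comparison via bridge-sampled log marginal likelihoods and
    posterior model probabilities; highest-density-interval group contrasts;
    posterior predictive simulation; and conventional behavioural metrics
    including perseverative/random/learning phase coding, errors to criterion,
    percent-correct measures, and win-stay/lose-shift analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    generics,
    coda
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
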