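Package: banditbg
Title: Basal Ganglia Models of Uncertainty-Driven Exploration in Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-fitting tools for studying how striatal
    GO/NO-GO learning combined with a dopaminergic novelty signal can implement
    uncertainty-driven exploration in multi-armed bandit tasks. Provides
    corticostriatal learning rules that track the mean and spread of reward
    distributions, dopamine novelty-response models that convert reward spread
    into posterior uncertainty, closed-form two-arm choice probabilities for
    directed, random and hybrid exploration strategies (plus Kalman-filter and
    classic upper-confidence-bound baselines), maximum-likelihood fitting of
    novelty-decay curves to firing-rate data and of trial-by-trial choice models
    to behavioural data with BIC/AIC comparison, synthetic data generators with
    known ground truth, and a bandit simulation harness with per-trial regret
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
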