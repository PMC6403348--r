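Package: conjrl
Title: Conjunctive Reinforcement Learning and Pattern Similarity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how value is learned over conjunctions of
    stimulus features. Implements a probabilistic target-detection task with
    overlapping compound stimuli (AB+, AC-, B-, C+), four reinforcement
    learning models of log reaction times (no-learning, base-rate, feature,
    conjunctive and value-spread learning), joint maximum-likelihood fitting
    with cross-validated predictive likelihood, random-effects Bayesian model
    selection with protected exceedance probabilities, construction of
    feature and conjunctive prediction-error regressors, pattern-similarity
    regression with permutation inference, and a localizer-template pattern
    content analysis. Synthetic-data generators provide behavior,
    multivoxel-like patterns, striatal activation estimates and localizer
    blocks with the statistical structure the analyses assume, so the full
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
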