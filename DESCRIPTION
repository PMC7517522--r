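Package: predstrat
Title: Inferring Prediction Strategies of Sequence-Learning Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating sequence-learning experiments with binary
    (or small finite-alphabet) order-R Markov stimuli and for inferring, by
    maximum likelihood, the prediction strategy of a probability-matching
    observer from the stimulus and the observer's trial-by-trial predictions.
    Implements Bayesian n-gram observers (MAP-order "argmax" and prior-weighted
    "average" strategies built on Dirichlet-multinomial evidence over Markov
    orders, with concentration, memory-discount and complexity-penalty
    parameters) and logistic-regression (GLM) observers; exact per-trial
    emission probabilities and prediction-stream log-likelihoods; the
    infinite-clone cross-entropy limit; grid-search maximum-likelihood
    estimation with identifiability (phi-ratio) intervals; and strategy-class
    confusion and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
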