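Package: attentionHSMM
Title: Explicit-Duration Hidden Semi-Markov Models for Latent Attentional
    State Estimation from Mixed Behavioral Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates latent binary attentional states from simultaneous
    binary trial outcomes and continuous response latencies using a two-state
    explicit-duration hidden semi-Markov model (HSMM) with mixed
    Bernoulli/lognormal emissions. Provides forward-backward EM inference
    with nonparametric or geometric state-duration distributions, maximum a
    posteriori state decoding, AIC/BIC-based model-order selection with
    predictive log-likelihood on held-out trials, a generative simulator
    (including nonstationary and first-order Markov variants), and a
    Monte-Carlo evaluation suite built around the relative improvement
    percentage (RIP) statistic and latency-distribution overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
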