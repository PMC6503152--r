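Package: betadcm
Title: Dynamic Causal Modelling of Beta-Power Transitions in a
    Thalamocortical Neural Mass Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying spontaneous transitions between low and
    high beta-band (15-35 Hz) power in parkinsonian motor cortex with a
    six-population thalamocortical neural mass model. The package builds
    candidate circuit models (9 thalamocortical wiring architectures
    crossed with 16 condition-modulation configurations), predicts
    per-condition power spectral densities from a delay-aware
    linearization of the circuit, extracts low/high beta data features
    from single-channel recordings by Hilbert-envelope percentile
    thresholding, fits models with a variational Laplace scheme,
    compares them by fixed-effects Bayesian model comparison with
    family inference, summarizes condition effects across subjects with
    a parametric empirical Bayes stage, and explores how condition
    effects shape normalized beta power. A synthetic-data module
    generates bursty electrocorticogram-like signals and model-based
    two-condition spectra with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
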