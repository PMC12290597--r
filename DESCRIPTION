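Package: neurodrift
Title: Neurally-Informed Hierarchical Drift-Diffusion Modelling of
    Perceptual Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how prior
    probability shapes perceptual decisions, combining single-trial EEG
    decoding with hierarchical Bayesian drift-diffusion modelling.
    Generates synthetic multichannel EEG epochs and choice/response-time
    data with known ground truth, decodes trial-wise face-versus-car
    evidence with sliding-window regularised logistic discriminators
    (leave-one-out cross-validated Az, permutation significance, forward
    scalp projections), and fits hierarchical Wiener diffusion models in
    which decoded component amplitudes regress onto drift rate or
    starting point, compared by the deviance information criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
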