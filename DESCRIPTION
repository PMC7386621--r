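Package: neuroassim
Title: Variational Data Assimilation for Conductance-Based Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Twin-experiment parameter estimation for conductance-based
    neuron models by constrained collocation. Synthesizes stimulation
    protocols and noisy membrane-voltage recordings from a seven-state
    rostral ventrolateral medulla (RVLM) neuron model, transcribes the
    model equations into Boole and Hermite collocation constraints, and
    estimates all 41 model parameters by sparse bound-constrained
    augmented-Lagrangian least squares. Includes a noise-amplitude ramp
    regularizer that escapes sub-optimal local minima through saddle-node
    bifurcations of the cost surface, Monte-Carlo posterior and
    covariance-spectrum analysis of estimated parameters, misfit-surface
    geometry (gradient, Hessian, noise-induced parameter offset), and
    prediction scoring on held-out protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
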