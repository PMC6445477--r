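Package: ratenet
Title: Timescales and Stability of Excitatory-Inhibitory Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recurrent excitatory-inhibitory rate networks in
    which every unit carries a hidden slow variable implementing either
    spike-frequency adaptation or synaptic filtering. Provides constant in-degree
    random connectivity generation with its spectral summaries, closed-form
    single-unit linear filters and their timescales, fixed points and
    population-averaged linear stability (saddle-node and Hopf boundaries),
    heterogeneous-mode stability via the mapping between network and connectivity
    eigenvalues (critical radius, bifurcation frequency and type), direct
    Euler-Maruyama simulation of the full network, a dynamical mean-field
    self-consistency solver based on Fourier synthesis of coloured Gaussian noise
    with damped iterative updates, and autocorrelation-based timescale estimators
    including an analytic-signal envelope width.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    tools,
    yaml,
    rlang
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
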