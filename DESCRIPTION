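Package: plaquesim
Title: Spatial Stochastic Dynamics of Oncolytic Virus Spread
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the spatial spread of an oncolytic virus
    through a growing monolayer of target cells. Provides a stochastic
    agent-based simulator of virus-cell dynamics on a two-dimensional lattice
    with Moore-neighborhood interactions, classifiers for the emergent plaque
    morphologies (hollow ring, filled ring, disperse, concentric rings) and
    their quadratic/linear growth laws, the local-neighborhood mass-action ODE
    theory whose equilibria predict the global outcome of the spatial system,
    an exact one-dimensional stochastic metapopulation model with
    reaction-diffusion front-speed estimates, Monte-Carlo phase-diagram
    scanning with analytic overlay lines, and least-squares fitting of the
    simulator to observed infected-cell time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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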