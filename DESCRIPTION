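Package: aoncb
Title: Subthreshold Moment Analysis of Conductance-Based Neurons with Synchronous Inputs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact stationary moment analysis and event-driven simulation of
    all-or-none-conductance-based (AONCB) neurons driven by synchronous
    synaptic inputs modeled as compound Poisson jump processes. Provides a
    PASTA-based engine for stationary mixed voltage moments of arbitrary
    order over feedforward neuron sets, the Marcus-rule event-driven
    simulator for the instantaneous-synapse limit (plus a finite synaptic
    time-constant Euler reference and gap-junction-coupled pairs), closed
    form small-weight approximations for voltage variance, cross-neuron
    correlation and skewness, and a Gaussian-copula/beta-marginal generator
    of correlated spike rasters with spike-time jittering and empirical
    spike-count correlation estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
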