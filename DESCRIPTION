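Package: servmort
Title: Small-Area Spatial Modelling of Mortality and Service Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for small-area (areal) analysis linking all-cause
    mortality to municipal service delivery. Builds a z-score composite
    service (non-)delivery index with a Gini coefficient of household
    income inequality, fits Besag-York-Mollie (BYM) convolution
    conditional-autoregressive spatial Poisson models by
    Metropolis-within-Gibbs MCMC with convergence diagnostics and DIC,
    flags mortality and service-delivery hotspots via posterior
    exceedance probabilities, and converts fitted relative risks into
    population attributable fractions and projected mortality
    reductions. Includes a synthetic areal data generator emulating the
    statistical structure of South African local-municipality data so
    the full pipeline is testable without survey microdata.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
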