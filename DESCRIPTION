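Package: pestPathways
Title: Markov Pathway Modelling of Invasive Pest Arrival through
    Container-Shipping Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds an absorbing first-order Markov pathway model of
    invasive-organism movement through a container-shipping network.
    Vessel route histories are decomposed into ordered origin-destination
    segments, segment traffic is rescaled into a substochastic
    transmission matrix with an explicit absorption column, and per-port
    arrival rates are estimated by Monte-Carlo pathway simulation, backed
    by an exact first-passage probability oracle for validation. Arrival
    rates are aggregated into rankings of destination ports, source ports
    and source countries, and the stability of those rankings is
    quantified under multiplicative, additive and edge-removal
    perturbations of the network. A synthetic route-history generator
    emulates the scale and hub structure of commercial vessel-movement
    extracts so the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
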