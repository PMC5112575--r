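Package: rootflow
Title: Soil Water Flow with Plant Root Water Uptake and Root-Parameter Search
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Implicit block-centered finite-difference solver for the
    one-dimensional Richards equation with a plant root water-uptake sink.
    Provides Feddes-type water-stress reduction with a transpiration-dependent
    ending potential, three selectable root uptake and compensation models,
    dynamic root growth, soil-evaporation limiting, layered soil hydraulic
    property models (tabulated and van Genuchten-Mualem), plain-text
    input/output dialects, a deterministic synthetic-scenario generator, and a
    simulation-based grid search that estimates the root distribution shape
    factor and maximum rooting depth from measured soil water content
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
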