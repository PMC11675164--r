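Package: sitnet
Title: Segregation-to-Integration Transformation Model of Memory Network Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator for the Segregation-to-Integration Transformation (SIT)
    model of memory evolution. Builds modular memory networks as coupled random
    regular communities, runs repeated reactivations consisting of stochastic
    cue-driven turn-on, deterministic linear-threshold activation spreading,
    and a Hebbian rewiring rule, and computes the structural metrics that
    track the transformation: the degree of integration, random-walker
    network entropy, the malleability index and its nonlinearity amplitude,
    and community tightness with its decay slope. Includes ensemble
    experiment protocols (full and single-community reactivation, parameter
    sweeps) with deterministic seed schedules and tidy results tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
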