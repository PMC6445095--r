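Package: wheatgap
Title: Wheat Ideotype Design and Yield-Gap Analysis with a Process-Based Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A daily-timestep, process-based winter wheat simulator
    (phenology, canopy dynamics, light interception, soil water cascade,
    grain filling), a seeded stochastic daily weather generator calibrated
    to long-run site climate statistics for wheat-growing sites in the
    United Kingdom and New Zealand, an evolutionary search algorithm with
    self-adaptation (EASA) that designs crop ideotypes by optimizing seven
    cultivar traits within observed genetic-variation bounds, and a
    pipeline estimating the yield gap between ideotype yield potential and
    a locally adapted reference cultivar under water-limited and irrigated
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
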