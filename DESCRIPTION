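Package: surf
Title: Agent-Based Simulation of Daily Urban Mobility and Footfall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based model of daily urban mobility in which
    heterogeneous agents (commuters and retired people) choose activities
    by comparing competing motivation intensities, move between
    function-tagged buildings over a street network using A* routing, and
    are counted by virtual footfall sensors. Provides tools to build
    synthetic towns and populations, run replicated simulations,
    summarise agent schedules against time-use-survey statistics, and
    compare simulated hourly footfall with observed sensor series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
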