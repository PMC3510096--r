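Package: reefsim
Title: Spatially Explicit Individual-Based Simulation of Coral Reef Benthic Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based, spatially explicit simulator of benthic space
    competition on a tropical coral reef. Four scleractinian coral species with
    massive or branching morphologies, fleshy macroalgae and algal turf compete
    for space on a continuous 40 x 40 m arena under thermal bleaching events,
    mechanical disturbance regimes and density-dependent herbivory. Coral
    colonies are 24-axis star agents with species-specific growth, reproduction
    via a stock-recruitment larval pool, and temperature-driven bleaching and
    mortality responses. The package provides the full monthly scheduler,
    a synthetic sea-surface-temperature generator with recurrent hot years,
    scenario sweeps over perturbation frequencies, and long-format cover output
    for community-composition analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
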