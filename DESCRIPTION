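Package: lakefcc
Title: Satellite-Driven Fish Potential Production and Carrying-Capacity
    Assessment for Lakes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the fish potential production (FPP) and the
    fish carrying capacity index (FCCI) of a single-species lake fishery from
    satellite ocean-colour style inputs.  Provides a seeded synthetic-scene
    generator with realistic shore/estuary chlorophyll structure, quality
    filtering and monthly compositing with a minimum-valid-days rule, the
    Vertically Generalised Production Model (VGPM) for depth-integrated
    primary production, a trophic energy-transfer chain from carbon fixation
    to fish fresh weight, hydroacoustic/gill-net biomass estimation, annual
    and spatial carrying-capacity indices with management zoning, matchup
    validation statistics (ARE, CC, RMSE, EA) with type II chlorophyll
    regression correction, and Monte Carlo propagation of trophic-parameter
    uncertainty.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
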