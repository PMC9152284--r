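Package: melkin
Title: Kinetic Modelling of Two-Phase Fed-Batch Mannosylerythritol Lipid Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of fed-batch mannosylerythritol lipid
    (MEL) fermentations with Ustilaginaceae fungi. Implements a two-phase
    kinetic model: a growth phase with dual-substrate (glucose/nitrate) Monod
    kinetics and exponential medium feeding, and a production phase coupling
    lipase-mediated oil hydrolysis with product inhibition, fatty-acid-to-MEL
    conversion, and intracellular lipid inclusion. Ships the published
    explicit-Euler integration scheme, process analytics (specific rates,
    yield coefficients, off-gas OUR/CER/RQ balances, crude-extract purity),
    elemental stoichiometry of the biomass, simulation-based parameter
    estimation, and a synthetic-data generator emulating sparse offline
    sampling and continuous off-gas streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
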