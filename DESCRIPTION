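Package: finstab
Title: Stability and Asynchrony Partitioning for Fishery Harvest Portfolios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the portfolio effect in multispecies
    fisheries and ecological communities from monthly time series.
    Partitions within-year stability of aggregate harvest or community
    biomass into species-level stability and asynchrony, and asynchrony
    further into statistical-averaging and compensation effects.  Includes
    harvest-portfolio indicators (seasonal harvest ratio around a fishery
    closure, harvest timing, fishing-effort and value-stability indices),
    design-based stratified trawl-survey biomass indices, piecewise
    structural equation models with directed-separation tests and Fisher's C
    (with AR(1) generalized least squares sub-models), interannual trend
    models with autocorrelated errors, and a synthetic-data generator that
    emulates a seasonally migrating demersal finfish community with
    closure-driven effort switching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    nlme,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
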