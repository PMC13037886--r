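Package: divloss
Title: Spatiotemporal Forecasting of Genetic Diversity Loss Under Habitat Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forecasts nucleotide diversity (pi) loss in spatially structured
    species after habitat loss. Implements an exact moment engine for the
    multideme Wright-Fisher model (pairwise identity-by-descent recursions
    under drift, migration and mutation; direct equilibrium solves and
    transient trajectories), habitat-change scenarios on deme grids (edge
    contraction, random fragmentation, gradual decline, restoration), a
    frequency-based forward Wright-Fisher simulator used as a stochastic
    oracle and genotype generator, empirical diversity statistics (pi,
    segregating sites, Hudson F_ST) on genotype matrices, in-silico extinction
    on geo-referenced samples, the genetic diversity-area relationship (GDAR)
    power law, FRAGSTATS-style landscape fragmentation metrics, and a pipeline
    translating conservation indicators (IUCN Red List categories, Living
    Planet Index declines, GBF Indicator 2 population counts) into short-,
    mid- and long-term pi-loss forecasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
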