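Package: swinescape
Title: Presence-Background Distribution Modelling of Invasive Wild Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A national-scale species distribution analysis for invasive wild
    pigs (Sus scrofa), built as a tested pipeline over synthetic landscapes.
    Provides a seeded synthetic-landscape generator (spatially autocorrelated
    habitat rasters, weather stations, contiguous watershed partitions, and
    multi-year occurrence polygons with rare long-distance introductions); a
    covariate engine deriving seven watershed-level habitat covariates
    (temperature day counts with adiabatic lapse-rate correction, April-1 snow
    depth, distance to perennial water, forest and forage cover, and a
    moving-window habitat-heterogeneity index); occurrence-polygon ingestion
    with introduction filtering and presence/background sample construction;
    an all-subsets logistic discrimination function with AICc shrinkage model
    averaging, unconditional standard errors, and variable-importance weights;
    RSF-plot-index k-fold cross-validation with quantile and equal-interval
    binning; and relative-occurrence-probability prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
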