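Package: phenorisk
Title: Temperature-Driven Insect Phenology Modelling and Establishment
    Risk Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits and evaluates temperature-response functions for insect
    life stages (development time distributions, development rates,
    mortality, fecundity, senescence), simulates deterministic
    stage-structured cohort life tables under diurnal temperature cycles
    reconstructed from monthly minimum/maximum grids, and maps three
    climate risk indices per grid cell: the establishment risk index
    (ERI), generation index (GI) and activity index (AI). Includes ESRI
    ASCII grid input/output, five-class suitability classification,
    continental area tabulation, climate-scenario change maps, and
    synthetic-data generators so the full pipeline runs without external
    climate downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
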