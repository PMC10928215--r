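Package: agbmapr
Title: Forest Aboveground Biomass Mapping from LiDAR Heights and Multi-Sensor Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for wall-to-wall forest aboveground biomass (AGB)
    mapping in the style of circa-2007 national carbon accounting studies:
    power-law allometry linking Lorey's height to AGB density, L-band SAR
    digital-number calibration to gamma-naught backscatter, C-band temporal
    statistics, optical NDVI compositing, LiDAR footprint filtering and
    grid-cell aggregation, region-stratified random-forest extrapolation with
    node-purity variable pruning, binned zero-intercept bias correction, and
    map validation and comparison statistics. A synthetic-scene generator
    emulates the statistical structure of the input data so the full pipeline
    is testable end to end without satellite archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ranger,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
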