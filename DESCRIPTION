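Package: landmosaic
Title: Landscape Pattern Metrics for Categorical Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes FRAGSTATS-style landscape metrics on categorical
    land-use/land-cover rasters. Segments patches by 4- or 8-connectivity,
    builds the class adjacency matrix, and derives patch-, class- and
    landscape-level metric tables (area/edge/shape/diversity/contagion
    families with area-weighted and other distribution statistics).
    Supports spatiotemporal series, buffer and buffer-ring gradients around
    a point or polygon, generic zonal decompositions and their combination,
    with tidy tables, trend plots, a deterministic synthetic-mosaic
    generator with brute-force oracles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
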