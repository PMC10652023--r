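Package: permalake
Title: Arctic Lake Drainage Detection and Drained Lake Basin Greening Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Object-based detection of permafrost lake drainage events from
    surface-water rasters, dating of each event by piecewise-linear temporal
    segmentation of annual water-index series, tracking of post-drainage
    vegetation greenness in drained lake basins against their surroundings,
    density and trend statistics across landscape strata, and gradient-boosted
    driver attribution with natively implemented permutation importance and
    sampling-based Shapley values. Ships a seeded synthetic-scene simulator
    with known lakes, drainage years, product noise and vegetation-recovery
    dynamics so the full pipeline is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
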