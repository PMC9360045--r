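Package: bloomsense
Title: Chlorophyll-a Soft-Sensing and Algal-Bloom Alarm Evaluation from Buoy Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers chlorophyll-a fluorescence (a proxy for algal and
    cyanobacterial biomass) from inexpensive high-frequency buoy measurements
    (water temperature, electrical conductivity, pH and system battery voltage)
    and raises WHO level-1 alerts at 10 ug/L. Provides range-based data
    cleaning with boundary snapping, trailing moving-window feature
    augmentation over 1-hour and 24-hour horizons, Yeo-Johnson plus
    standard-scaler normalization fitted per fold, order-preserving chunked
    K-fold validation with random hyperparameter search over ridge regression,
    regression trees and random forests against a training-mean baseline,
    regression and alarm (precision/recall/F1) evaluation per buoy and per
    calendar month, random-forest feature importance with named feature
    subsets, and a seeded synthetic two-buoy generator with seasonal blooms,
    diel cycles and sensor artifacts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    lubridate,
    readr,
    generics,
    withr,
    stats,
    utils,
    caret,
    ranger,
    rpart,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
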