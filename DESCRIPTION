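Package: hotspotcv
Title: Predicting Future Small-Area Hotspots of Preventable Hospitalisations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting which small geographic areas will be persistent
    hotspots of potentially preventable hospitalisations several years into the
    future. Classifies hotspots from directly age-sex standardised rates with
    Byar-approximation confidence limits, builds area-level prediction frames,
    enumerates a constrained all-subset space of Firth-penalised logistic models,
    evaluates them with an area-partitioned time-shifted repeated K-fold
    cross-validation that pools confusion counts across folds and repeats, and
    selects the model maximising positive predictive value subject to a minimum
    sensitivity. Includes a rolling-forecast-window comparison engine,
    current-hotspot and past-persistent-hotspot baseline rules, and a seeded
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
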