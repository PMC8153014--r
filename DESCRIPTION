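Package: peatstack
Title: Multi-Source Remote Sensing Classification of Tropical Peatland
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end workflow for landscape-scale land cover
    classification of tropical peatland from multi-source satellite
    imagery. Provides cloud scoring and 40-60 percentile-range
    compositing of optical time series, vegetation index and
    grey-level co-occurrence texture extraction, temporal backscatter
    amplitude and terrain features, recursive feature elimination with
    stratified 2-fold cross-validation, random forest classification
    with per-class Gini importance decomposition, majority filtering,
    and thematic-map accuracy assessment (user's/producer's/overall
    accuracy, F-scores, McNemar comparisons, area accounting). A
    seeded synthetic multi-sensor scene simulator with known ground
    truth allows the whole pipeline to run and be tested without any
    satellite data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    yaml,
    tiff,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
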