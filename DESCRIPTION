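Package: dynomodulon
Title: Time-Resolved iModulon Discovery from Promoter-Reporter Fluorescence
    Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts independently modulated promoter sets (iModulons) from
    high-temporal-resolution promoter-activity data of the kind produced by
    massively parallel microfluidic GFP-reporter assays. Raw fluorescence
    time series are background-corrected, median-filtered, normalized against
    a promoterless control, and converted into windowed log2 fold-change
    matrices. A robust ensemble of FastICA decompositions, condensed by
    density-based clustering and a repeat-consistency filter, yields
    reproducible components; promoter membership is determined by iterative
    D'Agostino K-squared thresholding, and each component is assigned a
    primary inducing condition and a temporal activation shape (fast,
    intermediate, steady). A synthetic-data generator with planted modules
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ica,
    withr,
    optparse
Config/testthat/edition: 3
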