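Package: rapemix
Title: Spectral Mixture Analysis Pipeline for UAV-Based Rapeseed Yield
    Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of six-band multispectral UAV imagery of
    rapeseed field trials: empirical-line radiometric calibration against
    in-scene reflectance panels, fully constrained least-squares spectral
    unmixing of each pixel against a five-endmember library (flower,
    sessile leaf, short-stalk leaf, wet soil, dry soil), vegetation-index
    computation, plot-level aggregation over rectangular regions of
    interest, and yield regression using vegetation-index-by-abundance
    products validated with averaged leave-one-out cross-validation. A
    fully ground-truthed synthetic-scene generator makes every stage
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
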