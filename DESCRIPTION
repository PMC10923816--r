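Package: emibrain
Title: Electromagnetic Brain-Scanner Pipeline for Stroke Detection and Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software pipeline for a portable electromagnetic (microwave) brain
    scanner: a 2-D Born-approximation scattering simulator for elliptical head
    phantoms with hemorrhagic or ischemic inclusions, two-phantom S-parameter
    calibration with scan-stability gating, a reflection-coefficient boundary
    regressor, and four complementary stroke detection and localization
    algorithms (horizontal-visibility-graph classifier ensemble with
    line-crossing maps, direct polar mapping, Green's-function beamography,
    and expected-value patch statistics), combined by image and decision
    fusion into a final stroke class (healthy, hemorrhagic, ischemic) and a
    quadrant call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    randomForest,
    e1071,
    caret,
    xgboost,
    png,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
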