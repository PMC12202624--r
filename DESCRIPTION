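Package: reefcover
Title: Coral Cover Estimation, Accuracy and Survey-Design Simulation for
    Citizen-Science Reef Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating benthic percent cover of coral
    morphology categories from image annotations (segmentation masks,
    expert polygons and 3x3 visual grids), for quantifying the accuracy
    of automated and citizen-science cover estimates against expert
    values, for fusing methods into a per-category "best" estimator, and
    for survey-design questions: Monte-Carlo resampling of images per
    site and analyses per image against a +/-5 percentage-point accuracy
    target, and per-reef-state-bin power analysis for detecting absolute
    differences in cover. Includes a hierarchical synthetic-data
    generator (reefs, sites, images, analysts) with known truth so the
    full pipeline is testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
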