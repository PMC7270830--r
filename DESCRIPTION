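Package: phenorow
Title: Plot and Plant Segmentation, Trait Extraction and Biomass
    Prediction for Spaced-Plant Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational phenotyping workflow for spaced-plant forage
    breeding trials imaged by multispectral drones and driven over by an
    ultrasonic height rig. Calibrates digital numbers to reflectance with
    empirical-line panels, computes NDVI, rectifies the ortho-mosaic on
    corner ground-control points, finds plant blocks and plant rows from
    1-D projection profiles (morphological opening, erosion and regional
    minima), grows under-estimated row boxes across inter-row gaps,
    detects individual plant centers by normalized cross-correlation
    template matching, splits rows into per-plant polygons, extracts
    per-plant NDVI and ultrasonic height, and predicts seasonal dry
    matter yield from an NDVI-squared-times-height predictor with
    plot-level aggregation and validation. A synthetic field-trial
    generator with full ground truth makes every stage testable without
    real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
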