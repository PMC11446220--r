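Package: wheatAGB
Title: Crop Height and Above-Ground Biomass Estimation from UAV Canopy
    Point Clouds and Multispectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for winter-wheat canopy phenotyping from UAV-derived
    data: accumulated-incremental-height (AIH) profiles and crop-height
    estimation from 3-D canopy point clouds, canopy height models
    (DSM - DEM) by kriging or inverse-distance rasterization, eighteen
    visible and multispectral vegetation indices, random-forest feature
    screening, and a benchmark of five regression algorithms (random
    forest, gradient boosting, XGBoost, support vector regression, ridge
    regression) for above-ground biomass estimation across growth stages.
    Includes a calibrated synthetic-field generator (layout, ground-truth
    traits, canopy and bare-ground point clouds, saturating band
    reflectances) so the full pipeline runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    MASS,
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
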