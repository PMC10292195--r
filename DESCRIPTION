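Package: biomeshift
Title: Stacked-Ensemble Biome Distribution Modelling with Spatial Blocking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the potential distribution of biomes from point
    observations and environmental covariate rasters using stacked
    generalization: random forest, gradient-boosted trees and a
    lasso-regularized multinomial linear model as base learners, combined by
    a multinomial logistic meta-learner trained on spatially blocked
    out-of-fold class probabilities. Provides 100 km block spatial
    cross-validation, log-loss skill scores, per-pixel class probability
    cubes with margin-of-victory and base-learner-spread uncertainty layers,
    aggregation of a 20-class biome legend to the six terrestrial IUCN
    biomes, confidence-filtered biome-transition detection between climate
    scenarios with exact spherical equal-area accounting, and a seeded
    synthetic-data generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
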