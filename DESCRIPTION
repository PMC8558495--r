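Package: aqrisk
Title: Rapid Ensemble Habitat-Suitability Risk Mapping for Aquatic Invasive Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An iterative machine-learning workflow for catchment-scale
    invasion risk mapping of aquatic invasive species. Converts point
    occurrence or genetic-admixture records and environmental raster
    time-series into per-catchment modelling tables (spatial thinning,
    temporal compositing, zonal averaging), screens covariates by Pearson
    correlation and iterative nonlinear feature-dependence pruning, trains
    a skill-weighted multi-model ensemble (GLM, classification tree,
    gradient boosting, random forest, XGBoost, neural network) for
    occurrence classification or admixture regression, culls degenerate
    members, and produces per-catchment suitability maps, change maps,
    prediction-uncertainty maps, multivariate environmental similarity
    (MESS) surfaces, and a tri-method ranking of environmental drivers
    (recursive feature elimination, permutation importance, backwards
    elimination) with partial-dependence curves. A synthetic landscape
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    nnet,
    pROC,
    purrr,
    ranger,
    rlang,
    rpart,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
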