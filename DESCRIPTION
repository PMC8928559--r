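Package: predchar
Title: Predictive Characterization of Crop Wild Relative Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecogeographic predictive characterization of
    georeferenced wild-plant populations. Builds ecogeographic land
    characterization (ELC) maps from gridded bioclimatic, edaphic and
    geophysic layers (random-forest variable importance, correlation
    pruning, k-means clustering with an elbow stopping rule), computes De
    Martonne aridity indices and rule-based soil texture and salinity
    classes, selects candidate abiotic-stress-tolerant subsets by
    environmental filtering with ELC-proportional capping, and models
    disease resistance from field evaluation scores with a suite of
    presence/absence algorithms evaluated by the True Skill Statistic,
    including permutation variable importance and suitability projection.
    A seeded synthetic-data generator with recorded ground truth supports
    end-to-end testing without external downloads.
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
    MASS,
    mgcv,
    nnet,
    randomForest,
    readr,
    rlang,
    rpart,
    splines,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
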