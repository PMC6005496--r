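Package: efasdm
Title: Multi-Scale Ensemble Species Distribution Modelling with Satellite-Derived Ecosystem Functional Attributes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing satellite-derived Ecosystem
    Functional Attributes (EFAs) against climate and land-cover predictors in
    ensemble species distribution models across spatial grains and extents.
    Includes a virtual-landscape and virtual-species generator with known
    truth, derivation of seasonal-dynamics metrics (productivity, seasonality,
    phenology) from composite satellite time series, bioclimatic and landscape
    predictors, collinearity screening, presence/pseudo-absence ensemble
    modelling with ROC-based thresholding, permutation variable importance,
    and categorical/continuous map-agreement statistics (fuzzy kappa,
    Spearman rank correlation, global Moran's I, overlay-area accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    glmnet,
    mgcv,
    rpart,
    randomForest,
    nnet,
    xgboost,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
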