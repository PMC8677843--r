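Package: geostackx
Title: Spatial Exploratory Statistics, Stacked-Ensemble Regression and
    Model-Agnostic Explanation for Areal Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for county-level (areal) epidemiological modelling:
    Getis-Ord Gi* hotspot statistics with seven-level Gi-bin classification,
    bivariate local Moran's I with conditional permutation inference, and the
    geodetector q-statistic for stratified spatial heterogeneity; Gi-bin
    stratified train/validation/test splitting; stacked-generalization
    regression over penalized-linear, random-forest, gradient-boosting and
    neural-network base learners tuned by random grid search with
    cross-validation and combined by a ridge meta-learner; model-agnostic
    explainers (permutation feature importance, partial, local and
    accumulated-local dependence profiles, two-variable partial dependence,
    additive break-down attributions) and per-unit attribution maps;
    reference spatial lag, spatial error and geographically weighted
    regression fits; and a synthetic county-lattice generator with spatially
    autocorrelated risk factors and a known response surface for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    xgboost,
    nnet,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
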