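Package: topofc
Title: Topological Analysis of Functional Brain Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Persistent-homology analysis of ROI-level functional MRI time
    series. Implements two complementary filtrations: Vietoris-Rips persistence
    of sliding-window (delay) embedded point clouds, and ordinary plus extended
    persistence of positively correlated connectivity graphs built from
    marginal and partial correlations. Persistence diagrams are compared with
    exact q-Wasserstein distances, summarised into inter-subject and inter-ROI
    distance matrices, tested for group differences with Wilcoxon rank-sum
    tests, and fed into two classifiers: a stacked ensemble on top-lifespan
    features and a hybrid dense-plus-convolutional network on inter-ROI
    distance matrices. A seeded synthetic-cohort generator with latent-factor
    AR(1) network structure makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    rpart,
    randomForest,
    ranger,
    e1071,
    caret,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
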