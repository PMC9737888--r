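Package: buckmat
Title: Buckwheat Maturity Prediction from Plot-Level RGB Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for predicting crop
    days-to-maturity from plot-level RGB canopy images, built around
    buckwheat phenology. Canopy is separated from soil by excess-green
    (ExG) conversion, two-cluster K-means and morphological cleanup; each
    plot-date yields a 22-dimensional feature vector (5 RGB vegetation
    indices, 9 HSV/HLS/Lab colour components, 8 texture statistics from
    the grey-level co-occurrence matrix, local binary patterns and Gabor
    filters). Calendar maturity labels are corrected by the canopy
    brown-pixel fraction, redundant features are pruned by Pearson
    correlation, and recursive feature elimination with cross-validation
    (RFECV) selects optimal feature subsets for six regression families,
    evaluated by correlation-based R-squared, RMSE and permutation
    feature importance. A synthetic scene generator reproduces the
    statistical structure of a real field campaign so every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    rpart,
    randomForest,
    ranger,
    xgboost,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
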