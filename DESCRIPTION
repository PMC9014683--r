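Package: rosie
Title: Robust Sparse Ensemble for Outlier Detection and Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble of three inherently different robust sparse binary
    classifiers -- sparse partial robust M-regression discriminant analysis,
    robust sparse K-means clustering, and trimmed elastic-net logistic
    regression -- for simultaneous detection of influential samples (outliers)
    and selection of discriminating features in high-dimensional (n << p)
    expression data.  Per-method outlyingness rankings are fused by the rank
    product statistic with exact tail p-values under the discrete-uniform
    null, FDR q-values flag influential samples, and features are selected by
    three-way intersection.  Includes a stratified block-bootstrap validity
    check and a three-scenario contamination simulation study with ROC/AUC
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
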