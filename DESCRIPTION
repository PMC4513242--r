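Package: conntensor
Title: Tensor Decomposition and Sparse Classification of Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stacks per-subject structural brain connectivity matrices into a
    three-way tensor and classifies diagnostic groups from them. Provides
    higher-order singular value decomposition (HO-SVD) with mode-wise
    truncation for tensor feature extraction, raw upper-triangle and SVD/PCA
    baseline features, L1-penalized logistic regression fit by accelerated
    proximal gradient, an undersampling-bagging evaluation protocol with
    cross-validated penalty selection, linear-model removal of age and sex
    confounds, five weighted global network measures, element-wise and
    metric-level group tests with Bonferroni correction, and a synthetic
    connectome cohort generator with planted group effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
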