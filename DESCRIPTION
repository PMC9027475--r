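Package: fliImpute
Title: Fast Linear Imputation for Expression Profiles by Simplex-Constrained
    Least Squares
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Imputes missing entries of a test expression profile as a convex
    combination of complete reference (training) profiles. The weights are
    obtained by nonnegative conjugate-gradient least squares (active-set
    restarted CGLS) with the sum-to-one constraint embedded in the objective
    as a stiff penalty row, so the imputed values always lie within the
    per-feature range of the training data. Ships zero/mean/unconstrained
    regression baselines, simplified lasso-neighbour and spectral-clustering
    comparators, seeded generators for digit-image and correlated
    multivariate-normal benchmark data, and an evaluation harness that traces
    classification retention (AUC/ACC/F1) and relative imputation error over
    a grid of missing-data fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Preprocessing, Classification
RoxygenNote: 7.3.3
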