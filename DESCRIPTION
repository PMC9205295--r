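Package: sparsekm
Title: Sparse Kernel Machines for Genome-Based Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel machines for genomic selection with sparse (Nystrom)
    kernel compression. Computes seven kernels (linear, polynomial, sigmoid,
    Gaussian, exponential and arc-cosine of any depth) on marker matrices,
    their symmetric square roots usable as design matrices by any supervised
    learner, and compressed designs built from an anchor subset of lines.
    Provides a unified fit/predict interface over gradient boosting, elastic
    net, support vector machines, random forest and bespoke Gibbs samplers
    for Bayesian ridge regression and GBLUP; nested cross-validation
    hyperparameter tuning by grid search or Bayesian optimization; regression
    and classification metric suites (including MAAPE and NRMSE); a
    multi-environment benchmarking protocol with per-environment and global
    summaries; and a synthetic marker/phenotype generator with known genetic
    architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    xgboost,
    lhs,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr
Config/testthat/edition: 3
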