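Package: metgp
Title: Multi-Environment Genomic Prediction with Environmental Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for multi-environment trials (METs).
    Implements an exhaustive environmental-index search (CERIS: sliding-window
    regression of environment-mean phenotypes on candidate weather windows),
    the classical reaction-norm framework (per-genotype intercept and slope on
    the index, predicted as derived traits), and a polygenic-environment-
    interaction (PEI) framework in which every marker carries a main effect
    and an index-interaction effect, fitted jointly across environments either
    in marker form or through the induced multi-environment kinship. A unified
    fit/predict contract covers fifteen estimators (GBLUP, the Bayesian
    alphabet, penalized regressions, kernel methods, and tree/margin
    learners), with cross-validation schemes for untested genotypes and for
    novel environments, plot-level heritability, and a seeded synthetic MET
    simulator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    e1071,
    randomForest,
    xgboost,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
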