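Package: stackle
Title: Stacked Generalization for Regression and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stacked generalization (stacking) with fold-wise base-learner
    training, out-of-fold meta-feature construction, and fold-model-averaged
    prediction. Base learners are declared as method names with hyperparameter
    tables; every table row is one base learner, and a grid helper builds full
    Cartesian combinations. The meta-learner can be trained once on the pooled
    out-of-fold predictions or once per fold, with per-fold meta predictions
    averaged (regression) or majority-voted (classification) at prediction
    time. Ships adapters for random forests ('ranger'), gradient boosting
    ('xgboost'), support vector machines ('kernlab'), elastic nets ('glmnet'),
    partial least squares ('mixOmics') and linear baselines, an extensible
    adapter registry, a synthetic-data generator with controlled
    signal-to-noise ratio, evaluation metrics (Pearson correlation, Cohen's
    kappa), a benchmark harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    yaml
Suggests:
    ranger,
    xgboost,
    kernlab,
    glmnet,
    nnet,
    mixOmics,
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
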