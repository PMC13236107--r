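Package: qensemble
Title: Quantum Ensemble Classifiers by Statevector Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Exact statevector simulation of quantum ensemble binary
    classifiers for small-sample problems: the swap-test quantum cosine
    classifier, quantum ensemble cosine classifiers that bag training
    samples in superposition through a control register (with either
    random sample-swap permutations or Haar-random unitaries), and
    shallow variational circuit ensembles (soft voting, bagging,
    boosting) trained with Adam via parameter-shift gradients. Includes
    Gaussian-blob and synthetic gene-expression benchmark generators,
    an evaluation harness (accuracy, weighted F1, Brier score, paired
    one-sided t-tests), and random forest / gradient boosting baselines
    with randomized and exhaustive hyperparameter search.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
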