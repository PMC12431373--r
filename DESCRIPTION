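Package: scsorf
Title: Sand Cat Swarm Optimized Random Forests for Clinical Tabular
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint feature selection and hyperparameter tuning of random
    forest classifiers on clinical tabular data using Sand Cat Swarm
    Optimization (SCSO), with repeated stratified train/test splits,
    fold-wise consolidation by feature union and hyperparameter majority
    vote, confusion-based evaluation metrics and diagnostics, exact
    Shapley attribution by subset enumeration, and diverse counterfactual
    search with a determinantal point process diversity term. Ships a
    synthetic generator emulating the 38-feature gallstone screening
    schema so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
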