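Package: hetsyn
Title: Multi-Task Heterogeneous-Network Learning for Drug Synergy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-drug-cell-line therapeutic synergy scores while
    jointly learning drug-drug adverse-effect labels as an auxiliary task.
    Drugs are encoded from a heterogeneous drug-target-protein network via
    meta-path instance enumeration, sequence aggregation (bidirectional
    GRU), attention-weighted instance extraction and a semantic-attention
    combiner, concatenated with chemical fingerprints. Includes a conic
    feed-forward synergy regressor with a gradient-stopped adverse-effect
    input, leakage-free pair-grouped evaluation, a reverse-mode automatic
    differentiation engine used to train the model end to end, and a
    seeded synthetic-data generator with a planted shared mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ChemmineOB,
    optparse,
    yaml
Config/testthat/edition: 3
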