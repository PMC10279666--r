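Package: snapshotFS
Title: Snapshot-Ensemble Deep Feature Selection for Histology Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains snapshots of a single convolutional network under a
    cyclic cosine-annealing learning-rate schedule, extracts and fuses
    penultimate fully-connected-layer deep features from the snapshots,
    selects a compact feature subset with binary particle swarm
    optimisation driven by a KNN-embedded accuracy/reduction fitness, and
    evaluates multi-class texture classification with confusion-matrix
    metrics, stratified cross-validation and McNemar's paired test.
    Includes gradient-weighted class-activation mapping for qualitative
    inspection of snapshot diversity, and synthetic generators (procedural
    texture images, planted-structure feature matrices) so the whole
    pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    class,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
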