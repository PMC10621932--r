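Package: hmlfsm
Title: Two-Phase Hybrid Feature Selection for Gene-Expression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid filter-wrapper gene selection for high-dimensional
    tumour/normal expression matrices. Phase 1 scores genes by information
    gain on MDL-discretized expression and refines the survivors with a
    genetic-algorithm wrapper driven by cross-validated classification
    accuracy; phase 2 ranks the phase-1 genes by minimum-redundancy
    maximum-relevance mutual information and optimizes the candidate pool
    with binary particle-swarm search. Includes a seeded synthetic microarray
    generator with planted informative and redundant genes, a six-classifier
    evaluation harness (confusion matrix, accuracy, precision, recall, F1,
    ROC AUC), and a reproducible end-to-end pipeline with plain-file stage
    artifacts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    nnet,
    randomForest,
    rpart,
    jsonlite,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
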