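Package: abxscreen
Title: Antibacterial Compound Prediction and Structural Novelty Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening pipeline for repurposing approved
    small-molecule drugs as antibacterial candidates. Parses a SMILES subset
    into molecular graphs, computes hashed path (FP2-analog) and circular
    (ECFP-analog) fingerprints with Tanimoto similarity, builds a curated
    activity benchmark (IC50 cutoff labelling, deduplication, molecular-weight
    and cross-class similarity filters, balanced negative resampling), trains
    a three-model consensus classifier (support vector machine, random forest,
    multi-layer perceptron) with grid search and repeated cross-validation,
    and screens drug libraries for consensus-active compounds that are
    structurally novel by fingerprint similarity and exact maximum-common-
    substructure scaffold matching. Includes a synthetic molecule generator
    with planted ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
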