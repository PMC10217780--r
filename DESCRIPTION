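Package: kgprodromal
Title: Knowledge-Graph Embeddings of EHR Data for Prodromal Disease Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a knowledge-graph-enriched electronic health record
    (EHR) prediction pipeline for prodromal (pre-diagnostic) disease risk.
    EHR concepts are mapped to nodes of a typed heterogeneous biomedical
    knowledge graph and propagated by personalized PageRank with a
    cohort-weighted restart distribution to give per-concept embedding
    vectors (PSEVs); summing and normalizing the PSEVs of a patient's
    concepts yields a patient signature over all graph nodes (SPOKEsig).
    The package provides pre-diagnostic cohort construction (index dates,
    exclusion rules, time-window restriction, prevalence-ratio sampling),
    weighted random-forest and logistic classification with bootstrap AUC
    confidence intervals, per-feature Mann-Whitney screening, a raw binary
    EHR baseline, a likelihood-ratio/age-prior prodromal-criteria baseline,
    patient-specific explanatory subnetworks, and a synthetic-data module
    that generates knowledge graphs and timestamped cohorts with
    controllable planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    ranger,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
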