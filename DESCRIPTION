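Package: chemsieve
Title: Machine-Learning Virtual Screening for Kinase Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based virtual-screening pipeline for kinase inhibitor
    discovery. Curates bioactivity tables (exact and censored records, salt
    forms, duplicates) into balanced, leakage-free train/test sets under
    lead-oriented and potency-oriented activity thresholds; encodes compounds
    as seven molecular representations (path, circular and substructure-key
    fingerprints, physicochemical descriptors, and hybrids); trains a
    five-algorithm model zoo (random forest, support vector machine with a
    Tanimoto kernel, k-nearest neighbours, Gaussian process, multi-layer
    perceptron) with grid search and stratified cross-validation ranked by
    the Matthews correlation coefficient; and screens compound libraries with
    probability-score thresholding, average-linkage diversity clustering and
    cluster-representative selection. A synthetic-data module generates
    ChEMBL-like activity tables, decoy and screening libraries with a planted
    substructure-activity signal so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    kernlab,
    ranger,
    ChemmineR,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse
SystemRequirements: OpenBabel (the obabel command-line tool)
Config/testthat/edition: 3
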