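Package: lineagescan
Title: Detection and Trait-Based Prediction of Hidden Genetic Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for flagging nominal species that harbour
    unrecognized ("hidden") genetic lineages from single-locus barcode
    alignments. Provides alignment quality control (nucleotide diversity
    screening, short-sequence removal), three single-locus species
    delimitation methods (barcode-gap distance partitioning, single-linkage
    merge-path gap scoring, and a single-threshold general mixed
    Yule-coalescent model on an ultrametric UPGMA tree), multi-method and
    multi-locus consensus classification, assembly of per-species geographic
    and environmental predictors with chained-equation predictive-mean-matching
    imputation, and a correlation-filtered random-forest classifier evaluated
    with exact binomial no-information-rate tests and Clopper-Pearson
    confidence intervals. A synthetic-world generator with planted lineage
    structure supplies ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    nnet,
    randomForest,
    caret
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
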