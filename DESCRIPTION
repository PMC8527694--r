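Package: SBBtools
Title: Sequence-Based Biomarker Extraction and Differential Abundance for 16S
    Amplicon Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Groups amplicon sequence variants (ASVs) by single- and
    multi-locus sequence-based biomarkers (SBBs) extracted from a multiple
    sequence alignment of their 16S rRNA sequences, aggregates relative
    abundances over the resulting (overlapping) microbial groups, and tests
    groups for differential abundance between case and control cohorts with
    a design-preserving permutation false discovery rate. Includes
    linkage-disequilibrium pruning of redundant biomarkers, hierarchical
    clustering of significant biomarkers against their carrier ASVs, a
    repeated-split random-forest phenotype-prediction benchmark, and a
    clade-structured synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Matrix,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    biomformat,
    jsonlite,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Microbiome, Sequencing, DifferentialAbundance, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SBBtools-package.R'
    'abundance.R'
    'variants.R'
    'biomarkers.R'
    'cluster.R'
    'differential.R'
    'io.R'
    'predict.R'
    'pipeline.R'
    'simulate.R'
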