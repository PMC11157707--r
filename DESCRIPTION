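Package: cfgastro
Type: Package
Title: Multi-Dimensional Cell-Free DNA Features and Stacked Ensemble
    Classification for Early Gastric Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extracts four families of whole-genome cell-free DNA (cfDNA)
    features from fragment-level sequencing summaries: GC- and library-size
    adjusted short/long fragment counts in 5-Mb bins (fragment size pattern),
    per-1-Mb-bin log2 depth ratios against a healthy baseline (copy number),
    GC-corrected fragment-midpoint coverage profiles around transcription
    factor binding sites (nucleosome coverage pattern), and 96-class
    trinucleotide substitution spectra from single-mismatch fragments.
    Combines the four feature blocks in a two-layer stacked ensemble
    classifier with cross-validated model selection, Youden-index
    thresholding and rank-based variable importance, and provides a Monte
    Carlo simulator of screening performance (true positives, false negative
    rate, negative predictive value) in a hypothetical population. A
    synthetic cfDNA cohort generator with known ground truth makes the whole
    pipeline testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    glmnet,
    xgboost,
    randomForest,
    nnet,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    Biostrings,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cfgastro-package.R'
    'cnv.R'
    'ensemble.R'
    'features.R'
    'fsp.R'
    'gcbias.R'
    'genome.R'
    'importance.R'
    'io-fragments.R'
    'ncp.R'
    'screening.R'
    'sns.R'
    'stats.R'
    'synthetic.R'
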