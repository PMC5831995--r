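Package: plantlincs
Title: Prediction of Long Intergenic Non-Coding RNAs in Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An SVM-based workflow for predicting long intergenic
    non-coding RNAs (lincRNAs) in plant transcriptomes. Computes
    coding-potential features (longest open reading frame length and its
    proportion of transcript length) together with 2-, 3- and 4-nucleotide
    pattern frequencies, selects the most class-discriminative patterns by
    principal component analysis, trains a radial-basis-function support
    vector machine with balanced classes, a stratified 80/20 split and
    10-fold cross-validated grid search, and applies a filtering cascade
    (coding-similarity removal, minimum length, intergenic placement
    against a gene annotation) whose SVM-positive calls are intersected
    with lncRNA-database annotation hits. Also implements a
    presence/absence differential-expression procedure across treated and
    control sequencing libraries, and seeded synthetic-data generators
    that emulate the statistical structure of the training and pipeline
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
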