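Package: degcnn
Title: Predicting Cold-Responsive Differential Expression from Regulatory Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for asking whether proximate regulatory DNA sequence predicts
    a gene's differential-expression response to cold across multiple natural
    genotypes. Provides a synthetic multi-accession genome simulator with
    planted cis-regulatory motifs and a logistic label model; strand-aware
    extraction and one-hot encoding of promoter/terminator windows; gene-family
    disjoint train/validation/test splitting with minority-class oversampling
    and a deterministic 5-bp spike-in positive control; a k-mer motif
    enrichment screen against a down-sampled control set with e-value stopping
    and PFM library matching; a random-forest baseline on transcription-factor
    binding-site count features with Altmann permutation importance; a compact
    convolutional-neural-network engine with hyperparameter grid search,
    validation-prAUC model selection, per-class accuracy metrics and
    label-permutation significance; and reporting statistics (Kolmogorov-
    Smirnov comparisons, rank-sum tests, mixed-effects hyperparameter models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    ranger,
    lme4,
    car,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
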