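Package: cdpexpress
Title: Predicting Recombinant Expressibility of Cysteine-Dense Peptides from
    Per-Residue Protein Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting whether a cysteine-dense peptide (CDP) can be
    expressed recombinantly in mammalian cells, starting from per-residue
    representations emitted by pretrained protein neural networks. Implements
    dataset ingestion and knottin/non-knottin partitioning, representation
    processing (best-of-run selection by mean pLDDT, pair-tensor reduction,
    concatenation, zero-padding, mean pooling), a random convolutional kernel
    transform over multichannel residue representations, random-forest and
    L2-regularized logistic-regression classifier heads, evaluation machinery
    (balanced stratified cross-validation, leave-one-out cross-validation with
    aggregated confidences, rank-based ROC AUC, permutation-based model ranking
    with critical-difference grouping, paired permutation tests, Mann-Whitney U),
    exact tree-path Shapley attributions aggregated into positional and
    per-representation importance profiles, and a synthetic data generator with
    plantable class signals so the whole pipeline is testable without any
    external embedding model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    glmnet,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
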