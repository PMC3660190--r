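Package: amfesnet
Title: Ensemble SVM Biomarker Selection and Mutual-Information Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Adaptive multiple-feature selection (AMFES) for expression-based
    biomarker discovery: ensemble linear-SVM gene ranking over random gene
    subsets, random-probe (artificial gene) relevance cutoffs, and adaptive
    optimal-subset selection by validation accuracy.  Downstream tooling
    builds gene relevance ("target") networks from Gaussian-kernel-density
    pairwise mutual information with a permutation-derived edge threshold,
    orders them by hierarchical clustering for clustergram display, and
    evaluates selected panels with cross-validated ROC/AUC.  A synthetic
    expression-data generator with planted informative genes and correlated
    blocks supports end-to-end verification against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
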