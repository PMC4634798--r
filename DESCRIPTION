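Package: otuselect
Title: Feature Subset Selection for Microbiome Abundance Tables
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Information-theoretic and sparse feature subset selection for
    feature-by-sample abundance tables (OTU or functional-feature counts).
    Implements plug-in estimators of entropy, mutual information and
    conditional mutual information on discretized abundances; a greedy
    forward-selection search over a catalog of nine filter criteria
    (MIM, MIFS, mRMR, JMI, CIFE, CMIM, ICAP, DISR, CondMI); a bootstrap
    Neyman-Pearson meta-selector (NPFS) that sizes the relevant set by a
    binomial tail test on per-feature selection counts; and an embedded
    selector via l1-penalized least squares on +/-1 coded phenotypes with a
    data-derived regularization grid and cross-validated choice of lambda.
    Reads BIOM 1.0 JSON (sparse or dense) and BIOM 2.1 HDF5 tables and
    QIIME-style tab-delimited mapping files, writes ranked-feature TSV
    output, and reports per-class mean relative abundances of selected
    features sorted by absolute between-class difference. Includes a seeded
    synthetic count-table generator with planted informative, redundant and
    parity-coupled (XOR) features for benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    biomformat,
    jsonlite,
    methods,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
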