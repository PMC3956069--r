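Package: grnbench
Title: Gene Regulatory Network Inference Methods and Simulation Benchmark
Version: 0.1.0
Authors@R:
    person("grnbench", "developers", email = "grnbench@example.org",
           role = c("aut", "cre"))
Description: A desk-scale benchmark suite for gene regulatory network
    inference from steady-state expression data. Implements sixteen
    unsupervised co-expression scoring methods (correlation flavours,
    CLR, ARACNE, PCIT, MRNET and MRNET-B, tree-ensemble importance,
    sigmoid regression, mass-distance, mutual rank, Euclidean distance
    and a generalized knockout z-score), a supervised and semi-supervised
    linear maximum-margin gene-pair classifier on outer-product features,
    a lightweight steady-state expression simulator for knockout,
    knockdown and multifactorial designs, and AUC-based evaluation of
    predicted topologies against gold-standard edge sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
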