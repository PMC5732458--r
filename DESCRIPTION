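Package: coregmod
Title: Co-Regulatory Module Detection in Directed Gene Regulatory Networks
Version: 1.0.0
Authors@R:
    person("CoReg", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies co-regulatory modules in directed gene regulatory
    networks by clustering genes on shared-neighbor similarity. Supports
    Jaccard, geometric and inverse log-weighted neighbor-overlap indices
    computed separately over in- and out-neighborhoods, complete-linkage
    hierarchical clustering with a hybrid dynamic tree cut, module
    classification into regulator, target and intermediate types, a
    planted-module network simulator and duplication-rewiring benchmarks
    with NMI, rewiring-recall and ROC/AUC scoring, and module co-expression
    significance testing by genome permutation or Fisher's combined
    probability test against an empirical pairwise null.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
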