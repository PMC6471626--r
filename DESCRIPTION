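Package: grangernet
Title: Directed Microbial Association Networks from Time Series via Granger Causality
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers directed association networks from microbial (and
    environmental) time series. Every ordered pair of variables is tested
    for Granger causality with nested lagged least-squares fits and an
    F-test; the family of p-values is corrected with Storey's q-value
    method; edges surviving the false discovery rate threshold are then
    screened with conditional Granger causality to remove spurious edges
    explained by a mediating variable. Includes abundance/prevalence
    filtering, listwise deletion of missing time points, an augmented
    Dickey-Fuller stationarity screen, a vector-autoregressive simulator
    with known causal structure for benchmarking, and Cytoscape-compatible
    network export (edge table, SIF, GraphML).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
biocViews: TimeCourse, Network, Microbiome, GraphAndNetwork, Metagenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
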