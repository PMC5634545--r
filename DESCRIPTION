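Package: subnetminer
Title: Discriminative Subnetwork Biomarker Mining from Functional Coherence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines connected functional subgraphs whose coherence pattern
    discriminates between two global session states (for example, high versus
    low learning rate). Builds session-specific functional networks from
    regional activity time series via band-limited wavelet coherence, derives
    binary learning-rate labels from exponential fits of behavioral curves,
    transforms the coherence clique into its edge-dual (line) graph, learns a
    one-dimensional discriminative projection regularized by the dual-graph
    Laplacian (sub-network learning), mines subgraphs conserved across
    repeated cross-validation, and scores them against a uniform null of
    random connected subgraphs with empirical p-values and Storey q-values.
    A fully synthetic study generator with planted discriminative subgraphs
    makes every stage testable without imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    minpack.lm,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
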