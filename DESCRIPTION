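Package: tknet
Title: Transkingdom Correlation Networks and Bipartite Betweenness Centrality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transkingdom multi-omic correlation networks
    (host transcriptomes, microbial amplicon sequence variants, bile acids,
    and metabolic phenotypes) from feature-by-sample tables, and infers
    candidate causal microbes via bipartite betweenness centrality (BiBC)
    scored against an Erdos-Renyi random-network null. Includes the
    preprocessing chain (counts-per-million, quantile normalization, log2
    with pseudocount, median normalization, qPCR delta-CT), per-feature
    differential statistics with a four-way treatment-effect classification,
    per-group Spearman correlation with Fisher-z fixed-effect meta-analysis,
    sign-based pruning of unexpected correlations, sparsity and sign-ratio
    network quality diagnostics, single-cell marker-based cell-type
    assignment of network genes, microbiota-dependence quadrant
    classification, and a synthetic multi-omic study generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    limma
Config/testthat/edition: 3
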