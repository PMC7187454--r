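Package: chromstates
Title: Chromatin-State Segmentation and Enhancer Dynamics Across Cell-State Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns multivariate Bernoulli hidden Markov chromatin-state
    models from binarized histone-mark tracks, decodes genome-wide
    segmentations, and quantifies chromatin-state dynamics between paired
    cell states such as mesenchymal stem cells and differentiated
    chondrocytes. Provides base-pair-level Jaccard similarity and
    hierarchical clustering of one chromatin state across many epigenomes,
    integration of CpG methylation tables with state maps including a
    Monte Carlo permutation chi-square test for enrichment of demethylated
    CpGs in enhancer states, classification of new versus constant
    enhancers, hypergeometric region-overlap tests, and position weight
    matrix scanning with Fisher-exact relative motif enrichment. A
    synthetic-data generator with full ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    IRanges,
    S4Vectors,
    Biostrings,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
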