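Package: wppina
Title: Weighted Protein-Protein Interaction Network Analysis with
    Experimental Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds literature-derived protein-protein interaction (PPI)
    networks from PSI-MI TAB 2.5 records with a replication-aware
    confidence score (method score, publication score and a CRAPome-based
    contaminant penalty), calls protein-microarray hits by duplicate-
    averaged Z-scores with negative-control subtraction, integrates the
    two networks into a common core with rescue re-scoring of
    sub-threshold literature interactions, filters interaction pairs by
    tissue co-expression at an RPKM threshold, and performs one-tailed
    hypergeometric GO biological-process enrichment with grouping of
    significant terms into semantic classes and functional blocks. A
    synthetic-fixture generator with planted ground truth makes the whole
    pipeline testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
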