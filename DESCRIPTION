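Package: evoaxis
Title: Evodevo-Axis Transcriptome Analysis with ANOM Profiles and
    Interactome Centrality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies whether a cell population's transcriptome is
    shifted toward unicellular (UC) or multicellular (MC) gene programs
    along the evodevo axis. Implements analysis-of-means (ANOM) decision
    limits, per-phylostratum evolutionary profiles with three-phase
    classification, the Transcriptome Age Index, multicellularity-index
    and Gene Ontology signature folds, stemness score-bin profiles,
    oncofetal per-gene comparisons, protein-interactome centrality
    (degree, stress, betweenness) stratified by evolutionary origin and
    pluripotency, differential-hub extraction with K-means module
    detection and neighborhood ('shell') propagation, and gene-wise PCA
    with gene-age correlation. Ships a synthetic-data generator that
    emulates a four-state polyploid cancer cell study so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
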