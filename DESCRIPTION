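Package: imidtf
Title: Prioritization of Transcription Factors Putatively Degraded by
    Immunomodulatory Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for prioritizing transcription factors
    (TFs) putatively degraded by immunomodulatory drugs (IMiDs: thalidomide,
    lenalidomide, pomalidomide). Combines multi-dataset differential-expression
    vote counting, a dual-evidence literature filter, TF-target regulon
    enrichment, C2H2 domain-class classification of candidates,
    embryonic-development over-representation filtering, and protein-network
    essentiality ranking (degree, harmonic closeness, betweenness, and maximal
    clique centrality). Includes readers and writers for the tabular dialects
    involved (evidence tables, STRING-style scored edge lists, TRRUST-style
    regulons, GMT gene sets, TF annotations) and a synthetic-scenario
    generator with planted degraded TFs and a planted network hub, so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
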