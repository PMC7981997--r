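Package: netpharm
Title: Network-Pharmacology Screening of Herbal Compounds Against Disease Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, re-usable implementation of the network-pharmacology
    workflow used to connect a medicinal herb's chemical constituents to a
    disease: drug-likeness screening of compounds (Lipinski, Ghose, Veber,
    Egan and Muegge rule systems plus the Abbott bioavailability score),
    filtering of predicted compound-target interactions, disease-gene
    selection by relevance score and top-decile differential expression,
    Venn-funnel intersections, typed compound-target(-pathway) network
    assembly with degree/betweenness/closeness topology, MCODE molecular
    complex detection on confidence-filtered protein-protein interaction
    networks, and hypergeometric gene-set over-representation analysis with
    Benjamini-Hochberg false-discovery-rate control. Includes seeded
    synthetic-data generators with planted ground truth for every input
    table, so the complete pipeline is testable offline.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
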