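Package: pelpscope
Title: Cross-Species Profiling of PELP1-Family Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening and characterisation of PELP1 (Proline-, Glutamic
    acid-, Leucine-rich Protein 1) protein families from sequence data.
    Classifies proteins into domain architectures from RIX1/NUC202 domain
    hit tables, computes amino-acid composition and fold-change enrichment
    against proteome background frequencies, quantifies LxxLL and PxxP
    short-linear-motif consensus by reference-anchored pairwise alignment,
    and builds percent-identity matrices with hierarchical clustering and
    Newick tree export. Includes a seeded synthetic-cohort generator with
    planted compositional biases, motif emissions, architectures and
    duplicates, so every stage of the pipeline is testable without any
    database downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
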