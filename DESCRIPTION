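Package: ednapipe
Title: Environmental DNA Metabarcoding Filtering and Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for vertebrate environmental DNA (eDNA)
    metabarcoding surveys: dual-tag demultiplexing and amplicon read
    processing into OTU tables, lowest-common-ancestor taxonomy
    assignment against a local reference set, a twelve-step true/false
    positive taxon-filtering framework driven by positive and negative
    controls and a regional occurrence list, community statistics
    (median-of-ratios normalization, Bray-Curtis dissimilarity, PERMANOVA,
    NMDS, group-average clustering, richness), and comparison of eDNA
    detections against visual dive surveys. Includes a synthetic-study
    generator that emulates a habitat-structured transect with filter
    replicates, mock-community positive controls, blank negative controls
    and contamination, so the whole cascade is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    S4Vectors,
    vegan,
    permute,
    ape,
    jsonlite
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
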