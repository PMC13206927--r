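Package: ibrtox
Title: Integrated Biomarker Response and Gene-Set Overlap Analysis for
    Network Toxicology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying overall toxicological impact across a
    biomarker battery with the Integrated Biomarker Response (IBR) index
    (per-biomarker standardization, direction-signed scoring, radar-polygon
    area), together with the gene-set operations that typically precede it
    in a network-toxicology study: normalization and intersection of
    compound-target and disease gene lists, hypergeometric overlap
    significance, local over-representation analysis against GMT
    annotations with Benjamini-Hochberg adjustment, and 2^-ddCt relative
    quantification. A seeded synthetic-data generator emulates multi-group
    biomarker panels and gene universes with planted overlaps and enriched
    terms so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
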