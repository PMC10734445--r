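Package: trichotraits
Title: Genome-Resolved Functional Trait Inference for Trichodesmium Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rule-based calling of iron-uptake and siderophore, phosphorus,
    nitrogen, vitamin, and bacterial-interaction traits from per-genome
    functional annotations (KEGG orthologs and PFAM domains) of
    metagenome-assembled genomes, as applied to the epibiont consortium of
    the marine diazotroph Trichodesmium. Provides a generic pathway
    completeness engine with marker-gene requirements and putative calls,
    marker-gene disambiguation of nitrate/nitrite reductases between
    assimilatory/dissimilatory nitrate reduction and denitrification,
    NIS/NRPS siderophore gene-cluster classification with nearest-reference
    typing, vitamin auxotrophy inference, consortium-level relative
    abundance, MinHash-sketch nucleotide identity with a re-occurrence rule,
    NSAF spectral-count normalization, and seeded synthetic-data generators
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
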