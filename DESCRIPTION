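Package: mitekit
Title: Annotation, Dating and Comparative Analysis of Miniature
    Inverted-Repeat Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for miniature inverted-repeat
    transposable elements (MITEs) in plant genomes. Detects candidate
    elements de novo as TIR-bounded, TSD-flanked sequences of 50-800 bp,
    clusters them into families with copy-number and flank-distinctness
    filters, classifies families into superfamilies from TSD/TIR
    signatures, scans genomes with curated seed libraries, dates
    insertions with the Kimura two-parameter model (T = K/2r), classifies
    orthologous insertion loci across related genomes as shared or
    species-specific from 1-kb flank homology, relates insertions to gene
    models and miRNA precursors, and scores annotations against a
    reference at nucleotide resolution. Ships a synthetic-genome
    simulator that plants elements with known family structure, age and
    orthology so every pipeline stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    data.table,
    ape,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
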