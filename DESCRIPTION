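Package: g4snp
Title: Locate SNP Variants and Map Them to Predicted G-Quadruplex Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Locates single-nucleotide variants given in HGVS cDNA notation
    within a gene's genomic sequence by exon-walking coordinate conversion,
    predicts G-quadruplex-forming regions with a G4Hunter-style sliding-window
    G-richness/G-skewness score, and annotates each variant with the
    overlapping or nearest predicted G-quadruplex and its distance from the
    start codon. Includes readers and writers for the tool's plain-text table
    dialects, a synthetic gene-model simulator with planted motifs and
    variants for ground-truth testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
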