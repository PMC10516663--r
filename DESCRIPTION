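Package: iresscope
Title: Detection, Structural Modeling and Typing of Dicistrovirus Intergenic-Region IRESs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate intergenic-region (IGR) internal ribosomal
    entry sites (IRESs) in dicistrovirus genomes and transcriptome fragments.
    Provides six-frame translation and ORF mapping to recognize the dicistronic
    genome layout, a descriptor-constrained backtracking search for the
    pseudoknotted IGR IRES architecture (including the compact Wenling-class
    "type 6e" fold with an H-type PKIII), nearest-neighbor free-energy
    evaluation of matched structures at 37 C, alignment-based covariation and
    conservation analysis of base-pair support, chemical-probing concordance
    checks, classification of IGR IRESs into types 6a-6e, and a ground-truthed
    generator of synthetic dicistronic genomes and compensatorily evolved
    sequence clades for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
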