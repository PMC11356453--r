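Package: flavotype
Title: Substrate-Preference Typing of Flavonol Synthase and Dihydroflavonol
    4-Reductase Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies flavonol synthase (FLS) and dihydroflavonol
    4-reductase (DFR) protein sequences by the amino acid residue at a
    substrate-preference determining position, located in homologs by
    reference-anchored global alignment (affine-gap Needleman-Wunsch,
    BLOSUM62). Screens candidates for functionality residues and wildcard
    protein motifs, builds neighbor-joining phylogenies with bootstrap
    support and iTOL-style type annotations, and quantifies the
    near-mutually-exclusive expression of FLS versus DFR across RNA-seq
    samples from kallisto-dialect abundance tables. Includes synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    patchwork,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
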