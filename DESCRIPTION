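Package: methylaid
Title: Guide Design and Quantification for RNA-Programmed Targeted CpG
    Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and analysis toolkit for targeted CpG methylation with
    dCas9-split-methyltransferase (M.SssI MN/MC) fusions. Implements the
    B-DNA helical-geometry model relating PAM-to-CpG gap length to the
    angular position of the methyltransferase fusion point, enumeration of
    NGG protospacers and CpG sites with gap-length pairing, an empirical
    gap-to-efficiency profile with strand combination and low/medium/high
    classification, pairwise interference rules for multiplexed sgRNAs, a
    seeded simulator of plasmid-like references with per-molecule
    methylation states, bisulfite conversion, short-read sampling and an
    FspI restriction-protection assay, and a toy-scale three-letter
    bisulfite aligner with per-cytosine strand-specific methylation
    calling and target/off-target summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
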