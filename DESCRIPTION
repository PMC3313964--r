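Package: barcodegap
Title: Evaluating DNA Barcoding Loci in Low-Divergence Plant Genera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for assessing the species-discrimination power
    of candidate DNA barcoding loci in genera with low interspecific
    divergence. Implements pairwise Kimura two-parameter (K2P) substitution
    rates with pairwise deletion, neighbor-joining trees with nonparametric
    bootstrap support, a monophyly-based species-discrimination criterion,
    leave-one-out identification through a seed-and-extend local aligner,
    barcode-gap statistics, column-level variability summaries, and an indel
    catalogue. A coalescent-flavoured synthetic-data generator reproduces the
    low-divergence, incomplete-lineage-sorting regime typical of temperate
    tree genera such as Fraxinus, so every pipeline stage is testable at
    desk scale without sequence downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    jsonlite,
    seqinr,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
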