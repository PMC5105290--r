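Package: phytophagr
Title: Comparative Genomics of Phytophagous Insect Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for the bespoke comparative-genomics analyses used in
    insect genome projects centred on phytophagy and xylophagy. Implements
    three-set orthologous-group partitioning with copy-number splits and homology
    fallbacks, a DNA-based bacterial-to-eukaryote horizontal gene transfer screen
    (E-value gating, bacterial-versus-animal comparison, junction confirmation,
    insertion age classification, flanking-gene reporting), InterPro-style
    domain-count gene-family expansion analysis, and exact-test differential
    expression flagging with quantile normalization and Benjamini-Hochberg false
    discovery rate control. A built-in Smith-Waterman local aligner with
    Karlin-Altschul E-values supports fully self-contained desk-scale runs, and
    simulators with known ground truth (gene-family birth-death on a species
    tree, planted bacterial insertions with junction evidence, planted domain
    expansions, negative-binomial count matrices) generate every input the
    pipeline reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
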