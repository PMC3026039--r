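Package: ltrscape
Title: Annotation and Evolutionary Analysis of LTR Retrotransposon Complements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, classifies and dates Ty3/gypsy-style LTR retrotransposon
    insertions in an assembled genome. A seed-and-extend gapped aligner scans
    the genome with family consensus sequences; candidate copies are assigned
    to families, classified as proviral or solo-LTR, screened for structural
    variation (indels >= 10 bp, duplications, target-site duplications), and
    dated by pairwise-deletion divergence from the consensus. Insertions are
    then stratified by chromatin compartment (pericentric and intercalary
    heterochromatin, pericentromeric and distal euchromatin), clustered,
    associated with gene models and summarized with enrichment chi-square
    tests, densities and divergence profiles. A synthetic-genome generator
    plants copies of known family, structure, age and location so that every
    stage of the pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
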