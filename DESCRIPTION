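Package: venomscreen
Title: Toxin Gene Discovery from Venom-Gland Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully testable re-implementation of a venom-gland
    transcriptome toxin-annotation workflow for caterpillar urticating-hair
    venoms. Provides translated Smith-Waterman homology search with
    Karlin-Altschul E-values, keyword plus dual-database differential
    filtering of candidate toxin genes with a venomous-taxon exception,
    gene-model completeness tagging and overlapping-fragment merging,
    an expression-ranked screen for novel secreted inhibitor-cystine-knot
    (knottin) peptides, FPKM expression summaries, single-linkage
    orthologous-family counting with chi-square gene-family expansion
    tests, distance-based neighbor-joining phylogenetics with bootstrap
    support and midpoint rooting, and a seeded synthetic-transcriptome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
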