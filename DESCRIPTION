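Package: mitorearr
Title: Mitogenome Composition, Gene-Order Rearrangement and
    Tandem-Duplication-Random-Loss Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing annotated insect mitochondrial
    genomes: nucleotide composition and strand skews, Nei-Gojobori (1986)
    nonsynonymous divergence under the invertebrate mitochondrial code,
    circular gene-order extraction and single-event rearrangement
    classification against the ancestral insect arrangement, intergenic
    spacer tandem-repeat decomposition and degenerate tRNA remnant
    detection by local alignment, exhaustive reconstruction of tandem
    duplication-random loss (TDRL) rearrangement scenarios ranked by
    pseudogene remnant evidence, and Fitch parsimony mapping of a
    rearrangement as a binary phylogenetic character.  Includes a
    synthetic mitogenome generator that plants rearrangements, tandem
    repeat units and divergence with a full truth log, so every stage of
    the pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
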