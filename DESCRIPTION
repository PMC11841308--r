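Package: promcons
Title: Conserved Transcription-Factor Binding Sites in Orthologous Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic-footprinting toolkit for plant promoters. Extracts
    TSS-anchored promoter windows from genome FASTA + GFF3, aligns them to
    promoters of orthologous genes with an exact affine-gap local aligner
    (CIGAR output, masked secondary alignments), scans promoters with
    position-weight matrices under a 0-order Markov background with analytic
    p-values, and calls a binding site conserved when its exact matched word
    recurs on the same strand within a fixed distance of the
    alignment-projected position in the ortholog promoter. Downstream
    statistics cover binned weighted regression of promoter similarity on
    protein identity, GO binomial enrichment with FDR control, TF-family
    occurrence tests, chi-square association with accessible chromatin, and
    variant intersection with accession-group summaries. A seeded synthetic
    scenario generator with planted ground truth makes every stage testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
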