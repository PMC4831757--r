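Package: ribodiverge
Title: Resampling Tests for Transcriptome and Translatome Divergence from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the transcriptome and translatome of two yeast
    strains from matched RNA-Seq and ribosome-footprint libraries. Implements
    composition-matched stratified resampling nulls for per-ortholog mRNA,
    footprint and translation-efficiency divergence with max-P aggregation and
    Benjamini-Hochberg FDR control; codon-level ribosome residence time over
    17-codon windows with permutation significance and a between-strain ratio
    test; evidence-based gene-model refinement; detection of translated
    N-terminal extensions and stop-codon read-through; and a synthetic
    two-strain data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    readr,
    stringr,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
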