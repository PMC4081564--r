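Package: splicemapr
Title: Impact of a Reference Transcriptome on Spliced RNA-Seq Read Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how annotation guidance changes
    short-read RNA-Seq alignment. Simulates a compact genome carrying the
    classic confounders of spliced alignment (retrotransposed pseudogenes,
    identical gene duplications, exons shorter than the read), aligns 75 bp
    reads with a transcriptome-guided and a de-novo seed-extend spliced
    aligner in unique or multiple reporting modes, and compares the two runs
    per read: Identical/Alternative/Unmapped categories, junction status,
    exon span, minimum overlap with an exon (MOE), intersection-strict gene
    counts, count-reduction reports and log2 fold-change concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
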