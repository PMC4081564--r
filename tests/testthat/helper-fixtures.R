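# Hand-built and cached fixtures shared across test files.

aln_row <- function(read_id, mapped = TRUE, chrom = "chr1", pos = 0L,
                    strand = "+", cigar = "75M", nm = 0L,
                    n_locations = 1L) {
  tibble::tibble(read_id = read_id, mapped = mapped,
                 chrom = if (mapped) chrom else NA_character_,
                 pos = if (mapped) as.integer(pos) else NA_integer_,
                 strand = if (mapped) strand else NA_character_,
                 cigar = if (mapped) cigar else NA_character_,
                 nm = if (mapped) as.integer(nm) else NA_integer_,
                 n_locations = as.integer(n_locations), secondary = FALSE)
}

# Two-exon gene plus an exact intronless retrocopy of its mRNA, built so the
# intron bases adjacent to the splice site disagree with the downstream exon
# (reads overhanging the junction by 1-3 bases mismatch the intron).
retro_fixture <- function(seed = 401) {
  withr::with_seed(seed, {
    ex1 <- random_dna(200); ex2 <- random_dna(200)
    intr <- random_dna(150)
    for (i in 1:3) {  # force disagreement at both intron ends
      b1 <- substring(ex2, i, i)
      substr(intr, i, i) <- sample(setdiff(c("A", "C", "G", "T"), b1), 1)
      b2 <- substring(ex1, 200 - 3 + i, 200 - 3 + i)
      substr(intr, 150 - 3 + i, 150 - 3 + i) <-
        sample(setdiff(c("A", "C", "G", "T"), b2), 1)
    }
    spacer1 <- random_dna(300); spacer2 <- random_dna(300)
    spliced <- paste0(ex1, ex2)
    genome <- stats::setNames(
      paste0(spacer1, ex1, intr, ex2, spacer2, spliced, random_dna(300)),
      "chrF")
    ann <- as_annotation(tibble::tibble(
      gene_id = "GP", transcript_id = "TP", chrom = "chrF", strand = "+",
      start = c(300L, 650L), end = c(500L, 850L)))
    list(genome = genome, annotation = ann, spliced = spliced,
         exon1 = c(300L, 500L), exon2 = c(650L, 850L),
         retro_start = 1150L)
  })
}

# Three-exon gene whose middle exon is 6 bp, flanked by unique sequence.
small_exon_fixture <- function(seed = 402) {
  withr::with_seed(seed, {
    ex1 <- random_dna(120); ex2 <- random_dna(6); ex3 <- random_dna(120)
    i1 <- random_dna(200); i2 <- random_dna(250)
    genome <- stats::setNames(
      paste0(random_dna(300), ex1, i1, ex2, i2, ex3, random_dna(300)),
      "chrE")
    starts <- c(300L, 300L + 120L + 200L, 300L + 120L + 200L + 6L + 250L)
    ends <- starts + c(120L, 6L, 120L)
    ann <- as_annotation(tibble::tibble(
      gene_id = "GS", transcript_id = "TS", chrom = "chrE", strand = "+",
      start = starts, end = ends))
    list(genome = genome, annotation = ann,
         spliced = paste0(ex1, ex2, ex3))
  })
}

# Cached seed-fixed full pipeline run shared by the heavier tests.
.run_cache <- new.env(parent = emptyenv())

cached_pipeline <- function() {
  if (is.null(.run_cache$bundle)) {
    .run_cache$bundle <- run_pipeline(
      file.path(tempdir(), "splicemapr-test-run"),
      sim = sim_config(seed = 101),
      quiet = TRUE)
  }
  .run_cache$bundle
}

# Smaller error-free run for the quantification dominance checks.
cached_errorfree <- function() {
  if (is.null(.run_cache$ef)) {
    sim <- sim_config(seed = 202, n_reads = 4000, error_rate = 0)
    g <- make_genome(sim)
    rd <- simulate_reads(g$genome, g$annotation, sim)
    cfg <- aligner_config()
    .run_cache$ef <- list(
      sim = sim, genome = g$genome, annotation = g$annotation,
      provenance = g$provenance, reads = rd$reads, truth = rd$truth,
      aln_a = align_guided(rd$reads, g$annotation, g$genome, cfg),
      aln_b = align_genome_only(rd$reads, g$genome, cfg))
  }
  .run_cache$ef
}
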