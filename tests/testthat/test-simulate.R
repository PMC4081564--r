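small_sim <- function(...) {
  sim_config(seed = 5, n_reads = 200, n_genes = 6,
             exon_length_range = c(50L, 120L),
             intron_length_range = c(60L, 200L),
             intergenic_length_range = c(200L, 400L), ...)
}

test_that("genome construction is deterministic and carries the confounders", {
  cfg <- small_sim()
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(as.data.frame(g1$annotation), as.data.frame(g2$annotation))

  prov <- g1$provenance
  expect_true("retrocopy" %in% prov$type)
  expect_true("identical_paralog" %in% prov$type)
  expect_true("gene_small_exon" %in% prov$type)

  # retrocopy: intronless, unannotated, Hamming distance exactly m to parent
  rc <- prov[prov$type == "retrocopy", ]
  parent_tx <- transcript_summary(g1$annotation)
  ptid <- parent_tx$transcript_id[parent_tx$gene_id == rc$parent]
  spliced <- transcript_sequence(g1$annotation, g1$genome, ptid)[[1]]
  retro_seq <- substring(g1$genome[[rc$chrom]], rc$start + 1L, rc$end)
  expect_equal(nchar(retro_seq), nchar(spliced))
  expect_equal(oracle_hamming(retro_seq, spliced), cfg$retrocopy_mutations)
  ann_ranges <- g1$annotation
  expect_false(any(ann_ranges$start >= rc$start & ann_ranges$end <= rc$end))

  # identical paralog: two annotated transcripts with equal mRNA
  pg <- prov[prov$type == "identical_paralog", ]
  par_tid <- parent_tx$transcript_id[parent_tx$gene_id == pg$parent]
  cop_tid <- parent_tx$transcript_id[parent_tx$gene_id == pg$element]
  seqs <- transcript_sequence(g1$annotation, g1$genome, c(par_tid, cop_tid))
  expect_equal(unname(seqs[1]), unname(seqs[2]))

  # small exon present as an internal exon
  se_gene <- prov$element[prov$type == "gene_small_exon"]
  se <- g1$annotation[g1$annotation$gene_id == se_gene, ]
  w <- se$end - se$start
  expect_true(cfg$small_exon_length %in% w[-c(1, length(w))])
})

test_that("different seeds give different genomes and read sets", {
  g1 <- make_genome(small_sim())
  g2 <- make_genome(sim_config(seed = 6, n_reads = 200, n_genes = 6))
  expect_false(identical(g1$genome, g2$genome))
})

test_that("error-free reads are exact transcript substrings with correct truth", {
  cfg <- small_sim(error_rate = 0)
  g <- make_genome(cfg)
  rd <- simulate_reads(g$genome, g$annotation, cfg)
  expect_equal(nrow(rd$reads), cfg$n_reads)
  expect_equal(nrow(rd$truth), cfg$n_reads)
  expect_true(all(rd$truth$n_errors == 0L))
  seqs <- transcript_sequence(g$annotation, g$genome)
  for (i in sample.int(cfg$n_reads, 40)) {
    tr <- rd$truth[i, ]
    expect_equal(rd$reads$seq[i],
                 substring(seqs[[tr$transcript_id]], tr$t_start + 1L,
                           tr$t_start + cfg$read_length))
  }
  # spans_junction <=> true_exon_span >= 2, and span agrees with projection
  expect_equal(rd$truth$spans_junction, rd$truth$true_exon_span >= 2L)
  for (i in sample.int(cfg$n_reads, 40)) {
    tr <- rd$truth[i, ]
    pr <- project_to_genome(g$annotation, tr$transcript_id, tr$t_start,
                            cfg$read_length)
    expect_equal(profile_from_cigar(pr$pos, pr$cigar)$exon_span,
                 tr$true_exon_span)
  }
})

test_that("a read covering an exon boundary is flagged as junction-spanning", {
  withr::with_seed(9, genome <- c(chr1 = random_dna(400)))
  ann <- as_annotation(tibble::tibble(
    gene_id = "G", transcript_id = "T", chrom = "chr1", strand = "+",
    start = c(0L, 150L), end = c(100L, 350L)))
  cfg <- sim_config(seed = 1, n_reads = 300, read_length = 75, error_rate = 0,
                    n_genes = 1)
  rd <- simulate_reads(genome, ann, cfg)
  # exon 1 occupies transcript [0, 100); junction iff t_start in (25, 100)
  expected <- rd$truth$t_start > 25L & rd$truth$t_start < 100L
  expect_equal(rd$truth$spans_junction, expected)
})

test_that("empirical substitution rate is within 3 binomial sd", {
  cfg <- sim_config(seed = 77, n_reads = 2000, error_rate = 0.005,
                    n_genes = 8)
  g <- make_genome(cfg)
  rd <- simulate_reads(g$genome, g$annotation, cfg)
  n_bases <- cfg$n_reads * cfg$read_length
  expect_gte(n_bases, 1e5)
  p_hat <- sum(rd$truth$n_errors) / n_bases
  sd3 <- 3 * sqrt(cfg$error_rate * (1 - cfg$error_rate) / n_bases)
  expect_lt(abs(p_hat - cfg$error_rate), sd3)
})

test_that("truth MOE on a two-exon transcript is discrete uniform on 1..37", {
  withr::with_seed(13, genome <- c(chr1 = random_dna(2000)))
  ann <- as_annotation(tibble::tibble(
    gene_id = "G", transcript_id = "T", chrom = "chr1", strand = "+",
    start = c(0L, 900L), end = c(800L, 1800L)))
  cfg <- sim_config(seed = 3, n_reads = 40000, read_length = 75,
                    error_rate = 0, n_genes = 1)
  rd <- simulate_reads(genome, ann, cfg)
  jr <- rd$truth[rd$truth$spans_junction, ]
  ol <- 800L - jr$t_start                     # overlap with the left exon
  moe <- pmin(ol, 75L - ol)
  expect_true(all(moe >= 1 & moe <= 37))
  gof <- suppressWarnings(
    stats::chisq.test(tabulate(moe, nbins = 37),
                      p = rep(1 / 37, 37)))
  expect_gt(gof$p.value, 0.01)
})
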