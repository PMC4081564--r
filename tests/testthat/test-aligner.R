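# Fixtures here are built so the expected alignments are derivable by hand
# (or by the brute-force oracles in helper-oracles.R).

retro_noretro_genome <- function(fx) {
  # same locus layout as retro_fixture but with the retrocopy blanked out by
  # truncation (parent gene region only)
  stats::setNames(substring(fx$genome[[1]], 1, 1150), names(fx$genome))
}

test_that("guided alignment reproduces the projected placement of an exact read", {
  fx <- retro_fixture()
  seqs <- transcript_sequence(fx$annotation, fx$genome, "TP")
  read <- tibble::tibble(read_id = "r1",
                         seq = substring(seqs[[1]], 171, 245))  # t_start 170
  aln <- align_guided(read, fx$annotation, fx$genome, aligner_config())
  expect_true(aln$mapped)
  expect_equal(aln$pos, 470L)
  expect_equal(aln$cigar, "30M150N45M")
  expect_equal(aln$nm, 0L)
  expect_equal(aln$strand, "+")
})

test_that("genome-only alignment maps exact contiguous and junction reads", {
  fx <- retro_fixture()
  genome <- retro_noretro_genome(fx)
  spliced <- fx$spliced
  reads <- tibble::tibble(
    read_id = c("contig", "junction"),
    seq = c(substring(genome[[1]], 331, 405),     # inside exon 1
            substring(spliced, 171, 245)))        # blocks 30/45
  aln <- align_genome_only(reads, genome, aligner_config())
  expect_equal(aln$cigar, c("75M", "30M150N45M"))
  expect_equal(aln$pos, c(330L, 470L))
  expect_equal(aln$nm, c(0L, 0L))
  # identical to the guided placement of the same junction read
  g <- align_guided(reads[2, ], fx$annotation, genome, aligner_config())
  expect_equal(g$cigar, aln$cigar[2])
  expect_equal(g$pos, aln$pos[2])
})

test_that("a MOE-1 junction read maps contiguously one base into the intron", {
  fx <- retro_fixture()
  genome <- retro_noretro_genome(fx)
  read <- tibble::tibble(read_id = "m1",
                         seq = substring(fx$spliced, 127, 201))  # OL 74, OR 1
  aln <- align_genome_only(read, genome, aligner_config())
  expect_true(aln$mapped)
  expect_equal(aln$cigar, "75M")
  expect_equal(aln$pos, 426L)
  expect_equal(aln$nm, 1L)  # the overhang base disagrees with the intron
})

test_that("reads of an identical gene duplication are dropped in unique mode and NH-2 in multiple", {
  ef <- cached_errorfree()
  prov <- ef$provenance
  pg <- prov[prov$type == "identical_paralog", ]
  ts <- transcript_summary(ef$annotation)
  tid <- ts$transcript_id[ts$gene_id == pg$parent]
  seqs <- transcript_sequence(ef$annotation, ef$genome, tid)
  # a read wholly inside one exon: contiguous and byte-identical in both loci
  ex <- ef$annotation[ef$annotation$transcript_id == tid, ]
  w <- ex$end - ex$start
  if (ex$strand[1] == "-") w <- rev(w)
  offs <- cumsum(c(0L, w))[seq_along(w)]
  pick <- which(w >= 75)[1]
  read <- tibble::tibble(read_id = "p1",
                         seq = substring(seqs[[1]], offs[pick] + 1,
                                         offs[pick] + 75))
  u <- align_guided(read, ef$annotation, ef$genome,
                    aligner_config(mode = "unique"))
  expect_false(u$mapped)
  expect_equal(u$n_locations, 2L)
  m <- align_guided(read, ef$annotation, ef$genome,
                    aligner_config(mode = "multiple"))
  expect_equal(nrow(m), 2L)
  expect_equal(m$n_locations, c(2L, 2L))
  expect_equal(m$secondary, c(FALSE, TRUE))
  expect_equal(dplyr::n_distinct(m$pos), 2L)
  # genome-only sees the same two byte-identical loci
  gu <- align_genome_only(read, ef$genome, aligner_config(mode = "unique"))
  expect_false(gu$mapped)
})

test_that("MOE threshold law: anchors gate de-novo junction recovery", {
  fx <- retro_fixture()
  genome <- retro_noretro_genome(fx)
  a <- 8L
  cases <- tibble::tibble(ol = c(8:14, 30, 37, 61, 67, 1, 2))
  cases$moe <- pmin(cases$ol, 75L - cases$ol)
  reads <- tibble::tibble(read_id = sprintf("t%02d", seq_len(nrow(cases))),
                          seq = substring(fx$spliced, 201L - cases$ol,
                                          275L - cases$ol))
  aln <- align_genome_only(reads, genome, aligner_config())
  truth_blocks <- vapply(cases$ol, function(ol) {
    sprintf("%d-%d,%d-%d", 500L - ol, 500L, 650L, 650L + 75L - ol)
  }, character(1))
  prof <- profile_from_cigar(ifelse(aln$mapped, aln$pos, 0L),
                             ifelse(aln$mapped, aln$cigar, "1M"))
  recovered <- aln$mapped & prof$blocks == truth_blocks
  expect_true(all(recovered[cases$moe >= a]))
  expect_false(any(recovered[cases$moe < 3L]))  # min(a, k_mismatch + 1) = 3
})

test_that("junction reads of a retrocopy parent are captured by the unannotated copy", {
  fx <- retro_fixture()
  # small-MOE read: fails de-novo anchoring, exact in the retrocopy
  read <- tibble::tibble(read_id = "rc1",
                         seq = substring(fx$spliced, 127, 201))
  b <- align_genome_only(read, fx$genome, aligner_config())
  expect_true(b$mapped)
  expect_equal(b$cigar, "75M")
  expect_equal(b$pos, fx$retro_start + 126L)
  expect_equal(b$nm, 0L)
  a <- align_guided(read, fx$annotation, fx$genome, aligner_config())
  expect_true(a$mapped)
  expect_equal(a$nm, 0L)
  expect_equal(a$cigar, "74M150N1M")
  expect_equal(a$pos, 426L)
})

test_that("guided alignment never loses an annotated read genome-only recovers at truth", {
  ef <- cached_errorfree()
  truth <- ef$truth
  L <- ef$sim$read_length
  # truth genomic blocks per read
  tb <- character(nrow(truth))
  for (tid in unique(truth$transcript_id)) {
    idx <- which(truth$transcript_id == tid)
    pr <- project_to_genome(ef$annotation, tid, truth$t_start[idx], L)
    tb[idx] <- profile_from_cigar(pr$pos, pr$cigar)$blocks
  }
  b <- ef$aln_b
  a <- ef$aln_a
  pb <- profile_from_cigar(ifelse(b$mapped, b$pos, 0L),
                           ifelse(b$mapped, b$cigar, "1M"))
  at_truth <- b$mapped & pb$blocks == tb
  expect_gt(sum(at_truth), 1000)
  pa <- profile_from_cigar(ifelse(a$mapped, a$pos, 0L),
                           ifelse(a$mapped, a$cigar, "1M"))
  expect_true(all(a$mapped[at_truth]))
  expect_true(all(pa$blocks[at_truth] == tb[at_truth]))
})

test_that("reported mismatch count equals the exhaustive-search minimum", {
  fx <- retro_fixture()
  expect_lte(nchar(fx$genome[[1]]), 10000)
  cfg <- aligner_config(mode = "multiple")
  withr::with_seed(31, {
    picks <- data.frame(t_start = sample(0:325, 8))
    reads <- tibble::tibble(
      read_id = sprintf("n%02d", 1:8),
      seq = vapply(picks$t_start, function(ts) {
        r <- substring(fx$spliced, ts + 1, ts + 75)
        nerr <- sample(0:2, 1)
        if (nerr > 0) {
          v <- strsplit(r, "")[[1]]
          for (p in sample.int(75, nerr)) {
            v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
          }
          r <- paste(v, collapse = "")
        }
        r
      }, character(1)))
    aln <- align_genome_only(reads, fx$genome, cfg)
    aln <- aln[!aln$secondary, ]
    for (i in seq_len(nrow(reads))) {
      want <- oracle_best_nm(reads$seq[i], fx$genome[[1]], cfg$min_anchor,
                             cfg$intron_range, cfg$k_mismatch)
      got <- aln$nm[aln$read_id == reads$read_id[i]]
      if (is.na(want)) {
        expect_false(aln$mapped[aln$read_id == reads$read_id[i]])
      } else {
        expect_equal(got, want)
      }
    }
  })
})

test_that("multiple mode caps reported placements at max_locations", {
  withr::with_seed(17, {
    unit <- random_dna(120)
    genome <- c(chrT = paste(rep(unit, 6), collapse = ""))
  })
  read <- tibble::tibble(read_id = "x", seq = substring(unit, 11, 85))
  m <- align_genome_only(read, genome,
                         aligner_config(mode = "multiple",
                                        max_locations = 4L))
  expect_equal(nrow(m), 4L)
  expect_equal(unique(m$n_locations), 6L)
  u <- align_genome_only(read, genome, aligner_config(mode = "unique"))
  expect_false(u$mapped)
  expect_equal(u$n_locations, 6L)
})
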