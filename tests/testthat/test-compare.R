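test_that("classification follows the three-category definition", {
  a <- aln_row("r1", pos = 1000L, cigar = "30M100N45M")
  expect_equal(classify_pair(a, a), "IDENTICAL")
  b_alt <- aln_row("r1", chrom = "chr7", pos = 2000L, cigar = "75M")
  expect_equal(classify_pair(a, b_alt), "ALTERNATIVE")
  b_un <- aln_row("r1", mapped = FALSE)
  expect_equal(classify_pair(a, b_un), "UNMAPPED")
  # different splice sites at the same start are ALTERNATIVE
  b_shift <- aln_row("r1", pos = 1000L, cigar = "29M100N46M")
  expect_equal(classify_pair(a, b_shift), "ALTERNATIVE")
  # block-wise comparison is robust to CIGAR spelling
  b_split <- aln_row("r1", pos = 1000L, cigar = "10M20M100N45M")
  expect_equal(classify_pair(a, b_split), "IDENTICAL")
})

test_that("strand disagreement is ALTERNATIVE, with an escape hatch", {
  a <- aln_row("r1", pos = 100L)
  b <- aln_row("r1", pos = 100L, strand = "-")
  expect_equal(classify_pair(a, b), "ALTERNATIVE")
  expect_equal(classify_pair(a, b, strand_matters = FALSE), "IDENTICAL")
})

test_that("classification domain errors are raised", {
  a <- aln_row("r1", pos = 100L)
  expect_error(classify_pair(a, aln_row("r2", pos = 100L)),
               "mismatched read ids")
  expect_error(classify_pair(aln_row("r1", mapped = FALSE), a),
               "mapped in run A")
})

test_that("classify agrees with an exhaustive field comparison oracle", {
  withr::with_seed(23, {
    for (i in 1:1000) {
      pos_a <- sample.int(5000, 1)
      left <- sample(5:70, 1)
      cg_a <- if (runif(1) < 0.5) "75M" else
        sprintf("%dM%dN%dM", left, sample(40:500, 1), 75 - left)
      a <- aln_row("r", pos = pos_a, cigar = cg_a,
                   chrom = sample(c("c1", "c2"), 1),
                   strand = sample(c("+", "-"), 1))
      b_mapped <- runif(1) < 0.8
      # half the time, perturb a copy of A; otherwise a fresh random record
      if (b_mapped && runif(1) < 0.5) {
        b <- a
        if (runif(1) < 0.5) b$pos <- b$pos + sample(c(0L, 0L, 1L), 1)
      } else {
        left_b <- sample(5:70, 1)
        b <- aln_row("r", mapped = b_mapped,
                     pos = sample.int(5000, 1),
                     cigar = if (runif(1) < 0.5) "75M" else
                       sprintf("%dM%dN%dM", left_b, sample(40:500, 1),
                               75 - left_b),
                     chrom = sample(c("c1", "c2"), 1),
                     strand = sample(c("+", "-"), 1))
      }
      expect_equal(classify_pair(a, b), oracle_classify(a, b))
    }
  })
})

test_that("category percentages and per-category statistics are correct", {
  a <- dplyr::bind_rows(
    aln_row("r1", pos = 0L, cigar = "30M100N45M"),
    aln_row("r2", pos = 200L), aln_row("r3", pos = 400L),
    aln_row("r4", pos = 600L), aln_row("r5", pos = 800L))
  b <- dplyr::bind_rows(
    aln_row("r1", pos = 0L, cigar = "30M100N45M"),
    aln_row("r2", pos = 200L), aln_row("r3", pos = 400L),
    aln_row("r4", pos = 9000L),
    aln_row("r5", mapped = FALSE))
  cmp <- compare_runs(a, b)
  s <- summarize_comparison(cmp)
  expect_equal(s$categories$pct, c(60, 20, 20))
  expect_equal(sum(s$categories$n), attr(cmp, "n_a_mapped"))
  # the single junction read is IDENTICAL: fraction 1 there, MOE histogram {30}
  idr <- s$categories[s$categories$category == "IDENTICAL", ]
  expect_equal(idr$junction_fraction, 1 / 3)
  expect_equal(s$moe$moe, 30L)
  expect_equal(s$moe$n, 1L)
  expect_equal(as.character(s$moe$category), "IDENTICAL")
})

test_that("exon-span matrix tallies categories per span", {
  a <- dplyr::bind_rows(
    aln_row("r1", pos = 0L, cigar = "20M50N55M"),
    aln_row("r2", pos = 500L, cigar = "20M50N55M"),
    aln_row("r3", pos = 1000L, cigar = "20M50N20M60N35M"))
  b <- dplyr::bind_rows(
    aln_row("r1", mapped = FALSE), aln_row("r2", mapped = FALSE),
    aln_row("r3", mapped = FALSE))
  s <- summarize_comparison(compare_runs(a, b))
  es <- s$exon_span
  expect_equal(es$n[es$span == "2" & es$category == "UNMAPPED"], 2L)
  expect_equal(es$n[es$span == "3" & es$category == "UNMAPPED"], 1L)
})

test_that("pairing semantics: denominators, absences, duplicates, warnings", {
  refs <- c(chr1 = 100000L)
  ids <- sprintf("r%02d", 1:12)
  a <- dplyr::bind_rows(
    lapply(1:10, function(i) aln_row(ids[i], pos = i * 100L)),
    aln_row(ids[11], mapped = FALSE),   # unmapped in A: uncategorized
    aln_row(ids[12], mapped = FALSE))
  b <- dplyr::bind_rows(
    lapply(1:7, function(i) aln_row(ids[i], pos = i * 100L)),
    lapply(8:9, function(i) aln_row(ids[i], pos = 9000L + i)),
    aln_row(ids[10], mapped = FALSE),
    aln_row(ids[11], mapped = FALSE))  # r12 absent from B entirely
  sam_a <- withr::local_tempfile(fileext = ".sam")
  sam_b <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, refs, sam_a)
  write_sam(b, refs, sam_b)
  cmp <- pair_runs(sam_a, sam_b)
  expect_equal(nrow(cmp), 10L)
  expect_equal(as.vector(table(cmp$category)), c(7L, 2L, 1L))
  expect_equal(attr(cmp, "n_a_unmapped"), 2L)

  dup <- dplyr::bind_rows(aln_row("r1", pos = 1L), aln_row("r1", pos = 2L))
  expect_error(compare_runs(dup, b), "unique-mode")

  empty_b <- aln_row("zz", mapped = FALSE)
  expect_warning(compare_runs(a[1:2, ] |> dplyr::mutate(), empty_b),
                 "no read ids shared")
})

test_that("secondary records are excluded from classification", {
  a <- aln_row("r1", pos = 100L)
  b <- dplyr::bind_rows(
    aln_row("r1", pos = 100L, n_locations = 2L),
    aln_row("r1", pos = 900L, n_locations = 2L) |>
      dplyr::mutate(secondary = TRUE))
  cmp <- compare_runs(a, b)
  expect_equal(as.character(cmp$category), "IDENTICAL")
})

test_that("partition invariant holds on randomized record sets", {
  withr::with_seed(29, {
    for (rep in 1:20) {
      n <- sample(5:60, 1)
      ids <- sprintf("q%03d", seq_len(n))
      a <- dplyr::bind_rows(lapply(seq_len(n), function(i)
        aln_row(ids[i], mapped = runif(1) < 0.8,
                pos = sample.int(1e4, 1))))
      b <- dplyr::bind_rows(lapply(seq_len(n), function(i)
        aln_row(ids[i], mapped = runif(1) < 0.7,
                pos = sample.int(1e4, 1))))
      cmp <- compare_runs(a, b)
      expect_equal(sum(table(cmp$category)), sum(a$mapped))
      expect_equal(nrow(cmp), attr(cmp, "n_a_mapped"))
    }
  })
})
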