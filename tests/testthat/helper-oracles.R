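# Independent oracles used to verify the package's fast paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-base brute-force projection: map every transcript offset of the window
# to its genomic base independently, then group consecutive positions into
# blocks.  Deliberately ignorant of the block arithmetic in the package.
oracle_project <- function(exon_start, exon_end, strand, t_start, len) {
  plus_pos <- unlist(mapply(function(s, e) seq(s, e - 1L), exon_start,
                            exon_end, SIMPLIFY = FALSE))
  if (strand == "-") plus_pos <- rev(plus_pos)
  g <- sort(plus_pos[(t_start + 1L):(t_start + len)])
  brk <- c(TRUE, diff(g) != 1L)
  block_id <- cumsum(brk)
  starts <- tapply(g, block_id, min)
  ends <- tapply(g, block_id, max) + 1L
  list(pos = unname(starts[1]),
       blocks = paste(paste0(starts, "-", ends), collapse = ","))
}

# Exhaustive field-by-field classification of a record pair.
oracle_classify <- function(rec_a, rec_b, strand_matters = TRUE) {
  if (!rec_b$mapped) return("UNMAPPED")
  ba <- cigar_blocks(rec_a$pos, rec_a$cigar)[[1]]
  bb <- cigar_blocks(rec_b$pos, rec_b$cigar)[[1]]
  same <- identical(rec_a$chrom, rec_b$chrom) &&
    nrow(ba) == nrow(bb) && all(ba == bb)
  if (strand_matters) same <- same && identical(rec_a$strand, rec_b$strand)
  if (same) "IDENTICAL" else "ALTERNATIVE"
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Exhaustive best-nm search over the genome-only candidate class: all
# contiguous placements, plus all two-block placements whose terminal
# anchor-length prefix/suffix are exact with the gap inside the intron
# range.  Plain string comparisons; no k-mer index, no prefix arrays.
oracle_best_nm <- function(read, genome_seq, anchor, intron_range, kmax) {
  best <- Inf
  n <- nchar(genome_seq)
  L <- nchar(read)
  for (q in c(read, revcomp(read))) {
    for (p in seq_len(n - L + 1L)) {
      mm <- oracle_hamming(substring(genome_seq, p, p + L - 1L), q)
      best <- min(best, mm)
    }
    pre <- substring(q, 1L, anchor)
    suf <- substring(q, L - anchor + 1L, L)
    pre_pos <- which(vapply(seq_len(n - anchor + 1L), function(p)
      substring(genome_seq, p, p + anchor - 1L) == pre, logical(1)))
    suf_pos <- which(vapply(seq_len(n - anchor + 1L), function(p)
      substring(genome_seq, p, p + anchor - 1L) == suf, logical(1)))
    for (p in pre_pos) {
      for (qq in suf_pos) {
        g <- qq + anchor - 1L - (p - 1L) - L
        if (g < intron_range[1] || g > intron_range[2]) next
        if (p + g + L - 1L > n) next
        for (bl in anchor:(L - anchor)) {
          mm <- oracle_hamming(substring(genome_seq, p, p + bl - 1L),
                               substring(q, 1L, bl)) +
            oracle_hamming(substring(genome_seq, p + bl + g,
                                     p + g + L - 1L),
                           substring(q, bl + 1L, L))
          best <- min(best, mm)
        }
      }
    }
  }
  if (best > kmax) NA_integer_ else as.integer(best)
}

random_transcript <- function(n_exons, max_coord = 1e5) {
  repeat {
    starts <- sort(sample.int(max_coord, n_exons))
    widths <- sample(5:80, n_exons, replace = TRUE)
    ends <- starts + widths
    if (all(starts[-1] > ends[-n_exons])) {
      return(list(start = as.integer(starts), end = as.integer(ends)))
    }
  }
}
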