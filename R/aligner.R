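# Toy spliced aligners: transcriptome-guided and genome-only seed-extend.
#
# Both enumerate substitution-only candidate placements (no indels) and then
# resolve them under a reporting mode: UNIQUE drops reads whose best score is
# tied across distinct genomic placements (recording the tie count), MULTIPLE
# reports all tied best placements up to a cap, with NH set to the tie count.
# Scoring is fewest mismatches, then fewer splices, then (genome-only)
# smallest intron; the remaining tie-break for deterministic ordering is
# leftmost coordinate then chromosome name.

#' Aligner configuration
#'
#' @param k_mismatch maximum substitutions per alignment.
#' @param seed_length k-mer length for the seeded contiguous search.
#' @param min_anchor minimum exact exonic block flanking a de-novo splice.
#' @param intron_range allowed length range for a de-novo intron (N gap).
#' @param mode `"unique"` or `"multiple"` reporting.
#' @param max_locations cap on reported placements in multiple mode.
#' @return an `aligner_config` list.
#' @export
aligner_config <- function(k_mismatch = 2L, seed_length = 20L,
                           min_anchor = 8L,
                           intron_range = c(40L, 50000L),
                           mode = c("unique", "multiple"),
                           max_locations = 2000L) {
  mode <- match.arg(mode)
  cfg <- list(k_mismatch = as.integer(k_mismatch),
              seed_length = as.integer(seed_length),
              min_anchor = as.integer(min_anchor),
              intron_range = as.integer(intron_range),
              mode = mode,
              max_locations = as.integer(max_locations))
  stopifnot(cfg$min_anchor >= 1, cfg$max_locations >= 1,
            cfg$k_mismatch >= 0, cfg$seed_length >= 1,
            cfg$intron_range[1] >= 1,
            cfg$intron_range[2] >= cfg$intron_range[1])
  class(cfg) <- "aligner_config"
  cfg
}

# Resolve candidate placements per read under the reporting mode.
# cands: tibble(read (index into reads), chrom, pos, strand, cigar, nm,
#               n_splice, intron)
resolve_candidates <- function(reads, cands, cfg, use_intron_in_score) {
  out_unmapped <- function(read_idx, nloc) {
    tibble(read_id = reads$read_id[read_idx], mapped = FALSE,
           chrom = NA_character_, pos = NA_integer_, strand = NA_character_,
           cigar = NA_character_, nm = NA_integer_,
           n_locations = as.integer(nloc), secondary = FALSE,
           seq = reads$seq[read_idx])
  }
  if (nrow(cands) == 0) {
    return(out_unmapped(seq_len(nrow(reads)), 0L))
  }
  cands <- distinct(cands, .data$read, .data$chrom, .data$pos, .data$strand,
                    .data$cigar, .keep_all = TRUE)
  score_intron <- if (use_intron_in_score) cands$intron else 0L
  cands <- cands |>
    mutate(.si = score_intron) |>
    group_by(.data$read) |>
    filter(rank_best(.data$nm, .data$n_splice, .data$.si)) |>
    mutate(n_best = n()) |>
    arrange(.data$pos, .data$chrom, .by_group = TRUE) |>
    ungroup()
  hit_reads <- sort(unique(cands$read))
  res <- list()
  uniq <- cands |> filter(.data$n_best == 1L)
  ties <- cands |> filter(.data$n_best > 1L)
  if (cfg$mode == "unique") {
    if (nrow(uniq) > 0) {
      res$mapped <- tibble(read_id = reads$read_id[uniq$read], mapped = TRUE,
                           chrom = uniq$chrom, pos = as.integer(uniq$pos),
                           strand = uniq$strand, cigar = uniq$cigar,
                           nm = as.integer(uniq$nm), n_locations = 1L,
                           secondary = FALSE, seq = reads$seq[uniq$read])
    }
    if (nrow(ties) > 0) {
      t1 <- ties |> distinct(.data$read, .data$n_best)
      res$ties <- out_unmapped(t1$read, t1$n_best)
    }
  } else {
    rep_rows <- cands |>
      group_by(.data$read) |>
      slice(seq_len(min(n(), cfg$max_locations))) |>
      mutate(.rank = row_number()) |>
      ungroup()
    res$mapped <- tibble(read_id = reads$read_id[rep_rows$read],
                         mapped = TRUE, chrom = rep_rows$chrom,
                         pos = as.integer(rep_rows$pos),
                         strand = rep_rows$strand, cigar = rep_rows$cigar,
                         nm = as.integer(rep_rows$nm),
                         n_locations = as.integer(rep_rows$n_best),
                         secondary = rep_rows$.rank > 1L,
                         seq = reads$seq[rep_rows$read])
  }
  no_hit <- setdiff(seq_len(nrow(reads)), hit_reads)
  if (length(no_hit) > 0) res$none <- out_unmapped(no_hit, 0L)
  bind_rows(res) |> arrange(match(.data$read_id, reads$read_id))
}

rank_best <- function(nm, n_splice, intron) {
  key <- nm * 1e12 + n_splice * 1e6 + intron
  key == min(key)
}

genome_candidates <- function(reads, genome, cfg) {
  contig <- cpp_contiguous_hits(unname(genome), reads$seq,
                                cfg$k_mismatch, cfg$seed_length)
  spl <- cpp_spliced_hits(unname(genome), reads$seq, cfg$min_anchor,
                          cfg$intron_range[1], cfg$intron_range[2],
                          cfg$k_mismatch)
  chroms <- names(genome)
  L <- nchar(reads$seq)
  parts <- list()
  if (nrow(contig) > 0) {
    parts$contig <- tibble(read = contig$read, chrom = chroms[contig$target],
                           pos = contig$pos, strand = contig$strand,
                           cigar = paste0(L[contig$read], "M"),
                           nm = contig$nm, n_splice = 0L, intron = 0L)
  }
  if (nrow(spl) > 0) {
    right <- L[spl$read] - spl$left_len
    parts$spliced <- tibble(read = spl$read, chrom = chroms[spl$target],
                            pos = spl$pos, strand = spl$strand,
                            cigar = paste0(spl$left_len, "M", spl$intron,
                                           "N", right, "M"),
                            nm = spl$nm, n_splice = 1L, intron = spl$intron)
  }
  bind_rows(parts)
}

#' Genome-only seed-extend spliced alignment
#'
#' Stage 1 enumerates every contiguous placement (both orientations) with at
#' most `k_mismatch` substitutions.  Stage 2 enumerates two-block spliced
#' placements anchored by exact placements of the read's `min_anchor`-base
#' prefix and suffix with a gap inside `intron_range` (at most one intron
#' per read).  Candidates are scored by fewest mismatches, contiguous
#' preferred over spliced, then smallest intron, and reported under the
#' configured mode.
#'
#' @param reads tibble with columns `read_id`, `seq`.
#' @param genome named character vector of chromosome sequences.
#' @param cfg an [aligner_config()].
#' @return alignments tibble (one row per record; several rows per read only
#'   in multiple mode, non-primary rows flagged `secondary`).
#' @export
align_genome_only <- function(reads, genome, cfg = aligner_config()) {
  stopifnot(inherits(cfg, "aligner_config"))
  if (nrow(reads) == 0) return(empty_alignments())
  cands <- genome_candidates(reads, genome, cfg)
  resolve_candidates(reads, cands, cfg, use_intron_in_score = TRUE)
}

#' Transcriptome-guided alignment with genomic fallback
#'
#' Phase 1 places each read (both orientations) on every spliced transcript
#' sequence with at most `k_mismatch` substitutions, projects each hit to a
#' genomic spliced alignment via the exon structure, and collapses duplicate
#' genomic placements (e.g. the same locus reached through two isoforms).
#' Reads with no transcriptome hit at all fall back to
#' [align_genome_only()].  Scoring is fewest mismatches then fewer splices;
#' reporting follows the configured mode.
#'
#' @inheritParams align_genome_only
#' @param annotation a `tx_annotation` tibble (the reference transcriptome).
#' @return alignments tibble.
#' @export
align_guided <- function(reads, annotation, genome, cfg = aligner_config()) {
  stopifnot(inherits(cfg, "aligner_config"))
  if (nrow(reads) == 0) return(empty_alignments())
  ann <- as_annotation(annotation)
  tx_ids <- unique(ann$transcript_id)
  if (length(tx_ids) == 0) return(align_genome_only(reads, genome, cfg))
  tx_seqs <- transcript_sequence(ann, genome, tx_ids)
  hits <- cpp_contiguous_hits(unname(tx_seqs), reads$seq,
                              cfg$k_mismatch, cfg$seed_length)
  cands <- NULL
  if (nrow(hits) > 0) {
    L <- nchar(reads$seq)
    # project transcript hits to genomic placements, per transcript
    hits$tx <- tx_ids[hits$target]
    proj <- hits |>
      group_by(.data$tx) |>
      dplyr::group_modify(function(df, key) {
        pr <- project_to_genome(ann, key$tx[[1]], df$pos, L[df$read])
        bind_cols(df, pr |> rename(gpos = "pos", gstrand = "strand"))
      }) |>
      ungroup()
    # read orientation '-' on a transcript flips the genomic strand
    gstrand <- ifelse(proj$strand == "+", proj$gstrand,
                      ifelse(proj$gstrand == "+", "-", "+"))
    cands <- tibble(read = proj$read, chrom = proj$chrom, pos = proj$gpos,
                    strand = gstrand, cigar = proj$cigar, nm = proj$nm,
                    n_splice = stringr::str_count(proj$cigar, "N"),
                    intron = 0L)
  } else {
    cands <- tibble(read = integer(), chrom = character(), pos = integer(),
                    strand = character(), cigar = character(),
                    nm = integer(), n_splice = integer(), intron = integer())
  }
  phase1_reads <- unique(cands$read)
  res1 <- resolve_candidates(reads[phase1_reads, , drop = FALSE],
                             cands |>
                               mutate(read = match(.data$read, phase1_reads)),
                             cfg, use_intron_in_score = FALSE)
  rest <- setdiff(seq_len(nrow(reads)), phase1_reads)
  if (length(rest) > 0) {
    res2 <- align_genome_only(reads[rest, , drop = FALSE], genome, cfg)
    res1 <- bind_rows(res1, res2)
  }
  res1 |> arrange(match(.data$read_id, reads$read_id))
}
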