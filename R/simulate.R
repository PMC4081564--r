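# Synthetic genome, annotation and read simulation.
#
# The generator builds a compact genome carrying the confounders that drive
# annotation-dependent mapping differences: multi-exon genes (2-8 exons), an
# unannotated retrotransposed pseudogene (intronless mutated copy of a parent
# transcript), a byte-identical tandem gene duplication (both copies
# annotated), and one gene with an internal exon shorter than the read.
# Reads are 75 bp single-end, sampled uniformly along transcripts with
# per-base substitution errors, with full ground truth.

#' Simulation configuration
#'
#' @param seed master RNG seed (integer).
#' @param read_length read length L in bases.
#' @param n_reads number of reads to simulate.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param n_genes number of ordinary multi-exon genes.
#' @param exon_length_range min/max exon length (bases) for ordinary exons.
#' @param small_exon_length length of the small internal exon (bases).
#' @param intron_length_range min/max intron length (bases).
#' @param retrocopy_mutations substitutions applied to the retrocopy.
#' @param exon_count_range min/max exons per ordinary gene.
#' @param intergenic_length_range min/max intergenic spacer length (bases).
#' @param include_retrocopies insert an unannotated processed pseudogene.
#' @param include_identical_paralog duplicate one gene's locus byte-identically.
#' @param include_small_exon_gene include a gene with the small internal exon.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       read_length = 75L,
                       n_reads = 20000L,
                       error_rate = 0.005,
                       n_genes = 30L,
                       exon_length_range = c(50L, 300L),
                       small_exon_length = 6L,
                       intron_length_range = c(60L, 2000L),
                       retrocopy_mutations = 2L,
                       exon_count_range = c(2L, 8L),
                       intergenic_length_range = c(500L, 1500L),
                       include_retrocopies = TRUE,
                       include_identical_paralog = TRUE,
                       include_small_exon_gene = TRUE) {
  cfg <- list(seed = as.integer(seed), read_length = as.integer(read_length),
              n_reads = as.integer(n_reads), error_rate = error_rate,
              n_genes = as.integer(n_genes),
              exon_length_range = as.integer(exon_length_range),
              small_exon_length = as.integer(small_exon_length),
              intron_length_range = as.integer(intron_length_range),
              retrocopy_mutations = as.integer(retrocopy_mutations),
              exon_count_range = as.integer(exon_count_range),
              intergenic_length_range = as.integer(intergenic_length_range),
              include_retrocopies = isTRUE(include_retrocopies),
              include_identical_paralog = isTRUE(include_identical_paralog),
              include_small_exon_gene = isTRUE(include_small_exon_gene))
  stopifnot(cfg$read_length >= 2,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$exon_length_range[1] >= 1,
            cfg$intron_length_range[1] >= 1,
            cfg$n_genes >= 1, cfg$n_reads >= 0)
  class(cfg) <- "sim_config"
  cfg
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# Build one gene locus; returns the locus sequence plus exon offsets local
# to the locus (0-based half-open).
build_locus <- function(exon_lens, intron_lens) {
  n <- length(exon_lens)
  pieces <- character(2 * n - 1)
  starts <- integer(n)
  off <- 0L
  for (i in seq_len(n)) {
    starts[i] <- off
    pieces[2 * i - 1] <- random_dna(exon_lens[i])
    off <- off + exon_lens[i]
    if (i < n) {
      pieces[2 * i] <- random_dna(intron_lens[i])
      off <- off + intron_lens[i]
    }
  }
  list(seq = paste(pieces, collapse = ""),
       exon_start = starts, exon_end = starts + exon_lens)
}

#' Generate a synthetic genome with annotation and provenance
#'
#' Lays out `n_genes` multi-exon genes (random strand) along one chromosome
#' separated by random intergenic spacers, then optionally appends: an
#' intronless copy of one parent gene's spliced transcript carrying exactly
#' `retrocopy_mutations` substitutions (recorded in the provenance table but
#' deliberately absent from the annotation — a processed pseudogene without a
#' gene model); a byte-identical second copy of another gene's locus, both
#' copies annotated as distinct genes; and one gene with an internal exon of
#' `small_exon_length` bases.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character), `annotation`
#'   (`tx_annotation` tibble) and `provenance` (tibble describing every
#'   placed element, including unannotated ones).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, "genome"), {
    chrom <- "chrS1"
    n <- config$n_genes
    pieces <- character(0)
    off <- 0L
    exon_rows <- list()
    prov <- list()
    add_piece <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      off <<- off + nchar(s)
    }
    spacer <- function() add_piece(random_dna(rint(1, config$intergenic_length_range)))

    special <- character(0)
    if (config$include_small_exon_gene) special <- c(special, "small_exon")
    gene_kind <- rep("ordinary", n)
    if (config$include_small_exon_gene && n >= 1) gene_kind[n] <- "small_exon"
    parent_retro_idx <- if (config$include_retrocopies) 1L else NA_integer_
    parent_para_idx <- if (config$include_identical_paralog) min(2L, n) else NA_integer_

    gene_meta <- vector("list", n)
    for (g in seq_len(n)) {
      spacer()
      kind <- gene_kind[g]
      if (kind == "small_exon") {
        n_ex <- max(3L, rint(1, config$exon_count_range))
        lens <- rint(n_ex, config$exon_length_range)
        mid <- 1L + sample.int(n_ex - 2L, 1)
        lens[mid] <- config$small_exon_length
      } else {
        n_ex <- rint(1, config$exon_count_range)
        lens <- rint(n_ex, config$exon_length_range)
      }
      intr <- rint(max(n_ex - 1L, 0L), config$intron_length_range)
      loc <- build_locus(lens, intr)
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("G%03d", g)
      tid <- sprintf("T%03d", g)
      exon_rows[[length(exon_rows) + 1L]] <- tibble(
        gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
        start = off + loc$exon_start, end = off + loc$exon_end)
      prov[[length(prov) + 1L]] <- tibble(
        element = gid, type = paste0("gene_", kind), chrom = chrom,
        start = off, end = off + nchar(loc$seq), strand = strand,
        parent = NA_character_)
      gene_meta[[g]] <- list(gid = gid, tid = tid, strand = strand,
                             locus_start = off, locus_seq = loc$seq,
                             exon_start = off + loc$exon_start,
                             exon_end = off + loc$exon_end)
      add_piece(loc$seq)
    }

    annotation <- as_annotation(bind_rows(exon_rows))
    genome1 <- setNames(paste(pieces, collapse = ""), chrom)

    # retrocopy: intronless, mutated copy of the parent's mRNA, unannotated
    if (config$include_retrocopies) {
      pm <- gene_meta[[parent_retro_idx]]
      spliced <- transcript_sequence(annotation, genome1, pm$tid)[[1]]
      if (config$retrocopy_mutations > nchar(spliced)) {
        abort("retrocopy_mutations exceeds parent spliced length")
      }
      retro <- mutate_bases(spliced, config$retrocopy_mutations)
      spacer()
      prov[[length(prov) + 1L]] <- tibble(
        element = paste0(pm$gid, "_retro"), type = "retrocopy", chrom = chrom,
        start = off, end = off + nchar(retro), strand = "+",
        parent = pm$gid)
      add_piece(retro)
    }

    # identical paralog: byte-identical copy of a gene's locus, annotated
    if (config$include_identical_paralog) {
      pm <- gene_meta[[parent_para_idx]]
      spacer()
      shift <- off - pm$locus_start
      gid2 <- paste0(pm$gid, "B")
      tid2 <- paste0(pm$tid, "B")
      exon_rows[[length(exon_rows) + 1L]] <- tibble(
        gene_id = gid2, transcript_id = tid2, chrom = chrom,
        strand = pm$strand,
        start = pm$exon_start + shift, end = pm$exon_end + shift)
      prov[[length(prov) + 1L]] <- tibble(
        element = gid2, type = "identical_paralog", chrom = chrom,
        start = off, end = off + nchar(pm$locus_seq), strand = pm$strand,
        parent = pm$gid)
      add_piece(pm$locus_seq)
    }
    spacer()

    genome <- setNames(paste(pieces, collapse = ""), chrom)
    annotation <- as_annotation(bind_rows(exon_rows))
    list(genome = genome, annotation = annotation,
         provenance = bind_rows(prov))
  })
}

# exon widths in transcript (5'->3') order
tx_exon_widths <- function(ex) {
  w <- ex$end - ex$start
  if (ex$strand[1] == "-") rev(w) else w
}

#' Simulate ground-truth-labelled reads from an annotation
#'
#' Draws each read by choosing a transcript with probability proportional to
#' its spliced length, a uniform start offset on the transcript, taking the
#' transcript-strand substring, and applying independent per-base
#' substitution errors at `config$error_rate`.  Truth records the source
#' transcript, offset, error count and the number of exons the read truly
#' overlaps.
#'
#' @param genome named character vector of chromosome sequences.
#' @param annotation a `tx_annotation` tibble; every transcript must have
#'   spliced length at least `config$read_length`.
#' @param config a [sim_config()].
#' @return list with `reads` (tibble `read_id`, `seq`) and `truth` (tibble
#'   `read_id`, `transcript_id`, `t_start`, `n_errors`, `true_exon_span`,
#'   `spans_junction`).
#' @export
simulate_reads <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$read_length
  ann <- as_annotation(annotation)
  txs <- transcript_summary(ann)
  if (any(txs$spliced_len < L)) {
    abort("every transcript must have spliced length >= read_length")
  }
  n <- config$n_reads
  if (n == 0) {
    return(list(reads = tibble(read_id = character(), seq = character()),
                truth = tibble(read_id = character(),
                               transcript_id = character(),
                               t_start = integer(), n_errors = integer(),
                               true_exon_span = integer(),
                               spans_junction = logical())))
  }
  seqs <- transcript_sequence(ann, genome, txs$transcript_id)
  withr::with_seed(stage_seed(config$seed, "reads"), {
    tx_idx <- sample.int(nrow(txs), n, replace = TRUE,
                         prob = txs$spliced_len)
    t_start <- floor(runif(n) * (txs$spliced_len[tx_idx] - L + 1))
    t_start <- as.integer(t_start)
    raw <- unname(substring(seqs[txs$transcript_id[tx_idx]], t_start + 1L,
                            t_start + L))
    n_err <- rbinom(n, L, config$error_rate)
    seq <- raw
    which_err <- which(n_err > 0)
    for (i in which_err) {
      seq[i] <- local({
        v <- strsplit(raw[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(L, n_err[i])
        for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
        paste(v, collapse = "")
      })
    }
    # true exon span from the spliced exon boundaries in transcript order
    bounds <- lapply(txs$transcript_id, function(tid) {
      cumsum(tx_exon_widths(exons_of(ann, tid)))
    })
    span <- vapply(seq_len(n), function(i) {
      b <- bounds[[tx_idx[i]]]
      s <- t_start[i]; e <- s + L
      sp_start <- c(0L, b[-length(b)])
      sum(sp_start < e & b > s)
    }, numeric(1))
    reads <- tibble(read_id = sprintf("r%06d", seq_len(n)), seq = seq)
    truth <- tibble(read_id = reads$read_id,
                    transcript_id = txs$transcript_id[tx_idx],
                    t_start = t_start,
                    n_errors = as.integer(n_err),
                    true_exon_span = as.integer(span),
                    spans_junction = span >= 2)
    list(reads = reads, truth = truth)
  })
}
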