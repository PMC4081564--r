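# Gene-level quantification impact: counting reads against the annotation
# under intersection-strict or union overlap resolution, the count-reduction
# report, and between-sample log2 fold-change concordance across runs.

#' Count reads per gene
#'
#' Intersection-strict mode (default): a read is counted for gene G iff every
#' aligned block lies entirely within the exons of at least one transcript of
#' G, and G is the only gene satisfying that — reads straddling an
#' exon-intron boundary or ambiguous between genes are discarded.  Union
#' mode: any block overlap with the exons of exactly one gene counts.
#' Counting ignores strand (unstranded library convention).
#'
#' @param alignments alignments tibble of unique-mode primary records.
#' @param annotation a `tx_annotation` tibble.
#' @param mode `"intersection-strict"` or `"union"`.
#' @return tibble `gene_id`, `count`, zero-filled over all annotated genes.
#' @export
count_genes <- function(alignments, annotation,
                        mode = c("intersection-strict", "union")) {
  mode <- match.arg(mode)
  ann <- as_annotation(annotation)
  aln <- normalize_alignments(alignments)
  if (any(aln$secondary) || anyDuplicated(aln$read_id[aln$mapped]) > 0) {
    abort("count_genes requires unique-mode primary records")
  }
  genes <- unique(ann$gene_id)
  zero <- tibble(gene_id = genes, count = 0L)
  aln <- aln |> filter(.data$mapped)
  if (nrow(aln) == 0 || nrow(ann) == 0) return(zero)
  bl <- cigar_blocks(aln$pos, aln$cigar)
  nb <- vapply(bl, nrow, integer(1))
  blocks <- tibble(aln_row = rep(seq_len(nrow(aln)), nb),
                   chrom = rep(aln$chrom, nb),
                   start = unlist(lapply(bl, function(b) b[, 1])),
                   end = unlist(lapply(bl, function(b) b[, 2])))
  type <- if (mode == "intersection-strict") "within" else "any"
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(blocks$start + 1L, blocks$end),
    IRanges::IRanges(ann$start + 1L, ann$end),
    type = type)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  same_chrom <- blocks$chrom[qh] == ann$chrom[sh]
  qh <- qh[same_chrom]; sh <- sh[same_chrom]
  if (length(qh) == 0) return(zero)
  ov <- tibble(aln_row = blocks$aln_row[qh],
               block_id = qh,
               transcript_id = ann$transcript_id[sh],
               gene_id = ann$gene_id[sh])
  if (mode == "intersection-strict") {
    # a transcript covers the read iff each of its blocks is within that
    # transcript's exon set
    per_tx <- ov |>
      distinct(.data$aln_row, .data$transcript_id, .data$gene_id,
               .data$block_id) |>
      count(.data$aln_row, .data$transcript_id, .data$gene_id,
            name = "n_blocks_hit") |>
      left_join(tibble(aln_row = seq_len(nrow(aln)), n_blocks = nb),
                by = "aln_row") |>
      filter(.data$n_blocks_hit == .data$n_blocks)
    gene_hits <- per_tx |> distinct(.data$aln_row, .data$gene_id)
  } else {
    gene_hits <- ov |> distinct(.data$aln_row, .data$gene_id)
  }
  assigned <- gene_hits |>
    group_by(.data$aln_row) |>
    filter(n() == 1L) |>
    ungroup()
  counts <- assigned |> count(.data$gene_id, name = "n_reads")
  out <- zero
  m <- match(counts$gene_id, out$gene_id)
  out$count[m] <- as.integer(counts$n_reads)
  out
}

as_count_tbl <- function(counts, label) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble(gene_id = names(counts), count = unname(counts))
  }
  counts <- as_tibble(counts)
  if (!all(c("gene_id", "count") %in% names(counts))) {
    abort(paste0(label, " must have columns gene_id and count"))
  }
  counts[, c("gene_id", "count")]
}

#' Per-gene count impact of the annotation-free run
#'
#' @param counts_a,counts_b per-gene count tibbles (`gene_id`, `count`) from
#'   the guided (A) and annotation-free (B) runs over the same read set;
#'   genes missing from either table are treated as zero.
#' @return a `gene_impact` tibble: `gene_id`, `count_a`, `count_b`,
#'   `reduction_pct` = `100 * (count_a - count_b) / count_a` (`NA` when
#'   `count_a` is 0).
#' @export
gene_impact <- function(counts_a, counts_b) {
  a <- as_count_tbl(counts_a, "counts_a") |> rename(count_a = "count")
  b <- as_count_tbl(counts_b, "counts_b") |> rename(count_b = "count")
  out <- dplyr::full_join(a, b, by = "gene_id") |>
    mutate(count_a = dplyr::coalesce(.data$count_a, 0L),
           count_b = dplyr::coalesce(.data$count_b, 0L),
           reduction_pct = ifelse(.data$count_a > 0,
                                  100 * (.data$count_a - .data$count_b) /
                                    .data$count_a,
                                  NA_real_))
  class(out) <- c("gene_impact", class(tibble()))
  out
}

#' Genes whose counts drop by at least a threshold without annotation
#'
#' @inheritParams gene_impact
#' @param threshold_pct minimum percent reduction (default 20).
#' @return tibble of genes with `count_a > 0` and
#'   `reduction_pct >= threshold_pct`, sorted by reduction descending.
#' @export
reduction_report <- function(counts_a, counts_b, threshold_pct = 20) {
  gene_impact(counts_a, counts_b) |>
    filter(.data$count_a > 0, .data$reduction_pct >= threshold_pct) |>
    arrange(dplyr::desc(.data$reduction_pct), .data$gene_id)
}

#' @method tidy gene_impact
#' @export
tidy.gene_impact <- function(x, ...) {
  as_tibble(x) |> arrange(dplyr::desc(.data$reduction_pct))
}

#' @method glance gene_impact
#' @export
glance.gene_impact <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_expressed_a = sum(x$count_a > 0),
         n_reduced_20pct = sum(x$count_a > 0 & x$reduction_pct >= 20,
                               na.rm = TRUE),
         total_a = sum(x$count_a), total_b = sum(x$count_b))
}

#' Between-sample fold-change concordance across runs
#'
#' For each gene, computes the log2 fold change between two samples under
#' each run, `log2((n1 + pseudocount) / (n2 + pseudocount))`, after an
#' optional library-size normalization that scales every count vector to
#' the mean total, and flags genes whose absolute fold-change difference
#' between the runs exceeds 2 (`blue`) or 3.3 (`red`), strict inequalities.
#'
#' @param counts_s1_a,counts_s2_a,counts_s1_b,counts_s2_b per-gene count
#'   tibbles for samples 1/2 under runs A/B (shared gene universe; missing
#'   genes count 0).
#' @param pseudocount added to normalized counts before the log ratio.
#' @param normalize scale count vectors to equal totals first.
#' @param thresholds named numeric, flag thresholds (`blue`, `red`).
#' @return a `fc_concordance` tibble: `gene_id`, `log2fc_a`, `log2fc_b`,
#'   `delta`, `flag` (factor none/blue/red).
#' @export
fc_concordance <- function(counts_s1_a, counts_s2_a, counts_s1_b,
                           counts_s2_b, pseudocount = 0.5,
                           normalize = TRUE,
                           thresholds = c(blue = 2, red = 3.3)) {
  tabs <- list(s1_a = as_count_tbl(counts_s1_a, "counts_s1_a"),
               s2_a = as_count_tbl(counts_s2_a, "counts_s2_a"),
               s1_b = as_count_tbl(counts_s1_b, "counts_s1_b"),
               s2_b = as_count_tbl(counts_s2_b, "counts_s2_b"))
  genes <- unique(unlist(lapply(tabs, function(t) t$gene_id)))
  mat <- vapply(tabs, function(t) {
    v <- setNames(as.double(t$count), t$gene_id)[genes]
    dplyr::coalesce(unname(v), 0)
  }, double(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(tabs)))
  if (normalize) {
    totals <- colSums(mat)
    target <- mean(totals)
    scale <- ifelse(totals > 0, target / totals, 1)
    mat <- sweep(mat, 2, scale, "*")
  }
  l2a <- log2((mat[, "s1_a"] + pseudocount) / (mat[, "s2_a"] + pseudocount))
  l2b <- log2((mat[, "s1_b"] + pseudocount) / (mat[, "s2_b"] + pseudocount))
  delta <- abs(l2a - l2b)
  flag <- factor(ifelse(delta > thresholds[["red"]], "red",
                        ifelse(delta > thresholds[["blue"]], "blue", "none")),
                 levels = c("none", "blue", "red"))
  out <- tibble(gene_id = genes, log2fc_a = unname(l2a),
                log2fc_b = unname(l2b), delta = unname(delta), flag = flag)
  class(out) <- c("fc_concordance", class(tibble()))
  out
}

#' @method tidy fc_concordance
#' @export
tidy.fc_concordance <- function(x, ...) {
  as_tibble(x) |> arrange(dplyr::desc(.data$delta))
}

#' @method glance fc_concordance
#' @export
glance.fc_concordance <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_blue = sum(x$flag != "none"),
         n_red = sum(x$flag == "red"),
         max_delta = if (nrow(x) > 0) max(x$delta) else NA_real_,
         cor_log2fc = if (nrow(x) > 1 && stats::sd(x$log2fc_a) > 0 &&
                          stats::sd(x$log2fc_b) > 0)
           stats::cor(x$log2fc_a, x$log2fc_b) else NA_real_)
}
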