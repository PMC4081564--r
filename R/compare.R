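# Per-read comparison of an annotation-guided run (A) against an
# annotation-free run (B).
#
# Every read mapped in run A is assigned one of three categories:
# IDENTICAL  - run B places it on the same chromosome and strand with the
#              identical ordered block list (splice sites included);
# ALTERNATIVE- run B maps it, but to a different region or with different
#              splice structure;
# UNMAPPED   - run B fails to map it.
# Reads unmapped in A are counted but never categorized; reads mapped only
# in B are likewise outside the categories (their count is retained).
# Block-wise comparison makes the check robust to CIGAR spelling; NM and
# other tags are deliberately ignored - placements are compared, not scores.

CATEGORIES <- c("IDENTICAL", "ALTERNATIVE", "UNMAPPED")

#' Compare two alignment runs per read
#'
#' @param aln_a alignments tibble from the guided run (run A); unique-mode
#'   primary records (duplicated primary read ids are an error).
#' @param aln_b alignments tibble from the annotation-free run (run B);
#'   reads absent from `aln_b` entirely are treated as unmapped in B.
#' @param strand_matters if `TRUE` (default) a strand disagreement alone
#'   makes a pair ALTERNATIVE.
#' @return a `run_comparison` tibble, one row per A-mapped read, with the
#'   category, both placements and run-A junction statistics
#'   (`exon_span_a`, `moe_a`).  Attributes: `n_a_mapped`, `n_a_unmapped`,
#'   `n_b_only` (reads mapped in B while unmapped in A).
#' @export
compare_runs <- function(aln_a, aln_b, strand_matters = TRUE) {
  a <- normalize_alignments(aln_a) |> filter(!.data$secondary)
  b <- normalize_alignments(aln_b) |> filter(!.data$secondary)
  if (anyDuplicated(a$read_id) > 0 || anyDuplicated(b$read_id) > 0) {
    abort("duplicate primary records per read id: comparison requires unique-mode runs")
  }
  a_mapped <- a |> filter(.data$mapped)
  n_a_unmapped <- sum(!a$mapped)
  b_map <- b |> filter(.data$mapped) |>
    select("read_id", chrom_b = "chrom", pos_b = "pos",
           strand_b = "strand", cigar_b = "cigar")
  n_b_only <- length(setdiff(b_map$read_id, a_mapped$read_id))
  if (nrow(a_mapped) > 0 && length(intersect(a_mapped$read_id, b$read_id)) == 0) {
    warn("no read ids shared between the two runs")
  }
  pa <- profile_from_cigar(a_mapped$pos, a_mapped$cigar)
  cmp <- a_mapped |>
    select("read_id", chrom_a = "chrom", pos_a = "pos",
           strand_a = "strand", cigar_a = "cigar") |>
    mutate(blocks_a = pa$blocks, exon_span_a = pa$exon_span,
           is_junction_a = pa$is_junction, moe_a = pa$moe) |>
    left_join(b_map, by = "read_id")
  if (nrow(cmp) > 0) {
    has_b <- !is.na(cmp$chrom_b)
    blocks_b <- rep(NA_character_, nrow(cmp))
    exon_span_b <- rep(NA_integer_, nrow(cmp))
    if (any(has_b)) {
      pb <- profile_from_cigar(cmp$pos_b[has_b], cmp$cigar_b[has_b])
      blocks_b[has_b] <- pb$blocks
      exon_span_b[has_b] <- pb$exon_span
    }
    same <- has_b & cmp$chrom_a == cmp$chrom_b & cmp$blocks_a == blocks_b
    if (strand_matters) same <- same & cmp$strand_a == cmp$strand_b
    cmp$blocks_b <- blocks_b
    cmp$exon_span_b <- exon_span_b
    cmp$category <- factor(
      ifelse(!has_b, "UNMAPPED", ifelse(same, "IDENTICAL", "ALTERNATIVE")),
      levels = CATEGORIES)
  } else {
    cmp$blocks_b <- character(0)
    cmp$exon_span_b <- integer(0)
    cmp$category <- factor(character(0), levels = CATEGORIES)
  }
  cmp <- cmp |> select("read_id", "category", dplyr::everything())
  attr(cmp, "n_a_mapped") <- nrow(a_mapped)
  attr(cmp, "n_a_unmapped") <- n_a_unmapped
  attr(cmp, "n_b_only") <- n_b_only
  class(cmp) <- c("run_comparison", class(tibble()))
  cmp
}

#' Classify one pair of alignment records
#'
#' Single-pair form of [compare_runs()] for record-level work: requires the
#' run-A record to be mapped and both records to carry the same read id.
#'
#' @param rec_a,rec_b one-row alignments tibbles.
#' @param strand_matters see [compare_runs()].
#' @return one of `"IDENTICAL"`, `"ALTERNATIVE"`, `"UNMAPPED"`.
#' @export
classify_pair <- function(rec_a, rec_b, strand_matters = TRUE) {
  if (rec_a$read_id != rec_b$read_id) {
    abort("record pair has mismatched read ids")
  }
  if (!rec_a$mapped) {
    abort("classification is defined only for reads mapped in run A")
  }
  cmp <- compare_runs(rec_a, rec_b, strand_matters = strand_matters)
  as.character(cmp$category[[1]])
}

#' Pair two SAM files and classify every guided-run-mapped read
#'
#' @param sam_a,sam_b paths to name-matched SAM files (A = guided run,
#'   B = annotation-free run).
#' @param strand_matters see [compare_runs()].
#' @return a `run_comparison` tibble (see [compare_runs()]).
#' @export
pair_runs <- function(sam_a, sam_b, strand_matters = TRUE) {
  compare_runs(read_sam(sam_a), read_sam(sam_b),
               strand_matters = strand_matters)
}

span_bin <- function(exon_span) {
  factor(ifelse(exon_span >= 4, "4+", as.character(exon_span)),
         levels = c("1", "2", "3", "4+"))
}

#' Summarise a run comparison
#'
#' Produces the four statistics families of the comparison: category counts
#' and percentages (of A-mapped reads), the same restricted to junction
#' reads, the exon-span-by-category breakdown, and the per-category MOE
#' histogram.  Junction status, exon span and MOE are taken from the guided
#' run's placements; the MOE histogram uses two-exon junction reads only.
#'
#' @param comparison a `run_comparison` tibble.
#' @return a `comparison_summary` list of tibbles: `categories`,
#'   `junction_categories`, `exon_span`, `moe`.
#' @export
summarize_comparison <- function(comparison) {
  cmp <- comparison
  n_tot <- nrow(cmp)
  cat_tbl <- cmp |>
    count(.data$category, .drop = FALSE) |>
    mutate(pct = if (n_tot > 0) 100 * n / n_tot else NA_real_)
  jn <- cmp |> filter(.data$is_junction_a)
  n_jn <- nrow(jn)
  jn_tbl <- jn |>
    count(.data$category, .drop = FALSE) |>
    mutate(pct = if (n_jn > 0) 100 * n / n_jn else NA_real_)
  cat_tbl <- cat_tbl |>
    left_join(jn_tbl |> select("category", n_junction = "n"),
              by = "category") |>
    mutate(junction_fraction = ifelse(.data$n > 0,
                                      .data$n_junction / .data$n, NA_real_))
  span_tbl <- cmp |>
    mutate(span = span_bin(.data$exon_span_a)) |>
    count(.data$span, .data$category, .drop = FALSE) |>
    group_by(.data$span) |>
    mutate(n_span = sum(.data$n),
           pct_within_span = ifelse(.data$n_span > 0,
                                    100 * .data$n / .data$n_span,
                                    NA_real_)) |>
    ungroup()
  moe_tbl <- cmp |>
    filter(.data$exon_span_a == 2L) |>
    count(.data$category, .data$moe_a, .drop = FALSE) |>
    filter(!is.na(.data$moe_a) | .data$n > 0) |>
    filter(!is.na(.data$moe_a)) |>
    rename(moe = "moe_a")
  out <- list(categories = cat_tbl, junction_categories = jn_tbl,
              exon_span = span_tbl, moe = moe_tbl,
              n_a_mapped = n_tot,
              n_junction = n_jn,
              junction_fraction_overall = if (n_tot > 0) n_jn / n_tot else NA_real_)
  class(out) <- "comparison_summary"
  out
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("Run comparison (", x$n_a_mapped, " guided-run-mapped reads, ",
      x$n_junction, " junction reads)\n\n", sep = "")
  print(x$categories)
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy run_comparison
#' @export
tidy.run_comparison <- function(x, ...) {
  summarize_comparison(x)$categories
}

#' @importFrom generics glance
#' @method glance run_comparison
#' @export
glance.run_comparison <- function(x, ...) {
  s <- summarize_comparison(x)
  ct <- s$categories
  pct <- setNames(ct$pct, ct$category)
  jf <- setNames(ct$junction_fraction, ct$category)
  tibble(n_a_mapped = s$n_a_mapped,
         n_a_unmapped = attr(x, "n_a_unmapped") %||% NA_integer_,
         n_b_only = attr(x, "n_b_only") %||% NA_integer_,
         pct_identical = pct[["IDENTICAL"]],
         pct_alternative = pct[["ALTERNATIVE"]],
         pct_unmapped = pct[["UNMAPPED"]],
         junction_fraction_overall = s$junction_fraction_overall,
         junction_fraction_identical = jf[["IDENTICAL"]],
         junction_fraction_alternative = jf[["ALTERNATIVE"]],
         junction_fraction_unmapped = jf[["UNMAPPED"]])
}
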