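# Gene-model container and GTF IO.
#
# An annotation is a tibble of exons in 0-based half-open genomic coordinates
# (one row per exon) with columns gene_id, transcript_id, chrom, strand,
# start, end, exon_rank (genomic order within the transcript).  The 1-based
# inclusive convention exists only at the GTF boundary.

#' Construct/validate an exon annotation
#'
#' Validates the invariants every downstream stage relies on: positive-width
#' half-open exons, a single chromosome and strand per transcript,
#' non-overlapping exons separated by at least one intronic base.
#'
#' @param exons data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `start`, `end` (0-based half-open).
#' @return a `tx_annotation` tibble, exons sorted by transcript and start,
#'   with an `exon_rank` column.
#' @export
as_annotation <- function(exons) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  missing <- setdiff(need, names(exons))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ann <- as_tibble(exons)[, need]
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  if (nrow(ann) > 0) {
    if (any(ann$start < 0) || any(ann$end <= ann$start)) {
      abort("exons must satisfy start >= 0 and end > start (half-open)")
    }
    if (!all(ann$strand %in% c("+", "-"))) {
      abort("strand must be '+' or '-'")
    }
    bad <- ann |>
      group_by(.data$transcript_id) |>
      summarise(one_chrom = dplyr::n_distinct(.data$chrom) == 1L,
                one_strand = dplyr::n_distinct(.data$strand) == 1L,
                one_gene = dplyr::n_distinct(.data$gene_id) == 1L,
                .groups = "drop") |>
      filter(!.data$one_chrom | !.data$one_strand | !.data$one_gene)
    if (nrow(bad) > 0) {
      abort(paste0("transcript(s) with inconsistent chrom/strand/gene: ",
                   paste(bad$transcript_id, collapse = ", ")))
    }
    ann <- ann |>
      arrange(.data$transcript_id, .data$start) |>
      group_by(.data$transcript_id) |>
      mutate(exon_rank = row_number()) |>
      ungroup()
    # exons must be disjoint with a gap of >= 1 base (an intron) between
    # consecutive exons: start[i+1] >= end[i] + 1
    gap_bad <- ann |>
      group_by(.data$transcript_id) |>
      summarise(bad = n() > 1 && any(.data$start[-1] < .data$end[-n()] + 1L),
                .groups = "drop") |>
      filter(.data$bad)
    if (nrow(gap_bad) > 0) {
      abort(paste0("transcript(s) with overlapping or abutting exons: ",
                   paste(gap_bad$transcript_id, collapse = ", ")))
    }
  } else {
    ann$exon_rank <- integer(0)
  }
  class(ann) <- c("tx_annotation", class(tibble()))
  ann
}

#' Read a UCSC-dialect GTF into an exon annotation
#'
#' Parses exon feature lines of a GTF as produced by the UCSC Table Browser
#' (9 tab-separated columns, `gene_id`/`transcript_id` attributes, 1-based
#' inclusive coordinates) and returns the 0-based half-open annotation tibble.
#' Non-exon feature lines and `#` comments are ignored.  Malformed exon lines
#' raise an error naming the line number; transcripts with overlapping exons
#' fail validation.
#'
#' @param path path to a GTF file.
#' @return a `tx_annotation` tibble (see [as_annotation()]).
#' @export
read_gtf <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  rows <- vector("list", length(keep))
  ri <- 0L
  for (i in keep) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      abort(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
                    i, length(f)))
    }
    if (f[3] != "exon") next
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || start1 < 1 || end1 < start1) {
      abort(sprintf("GTF parse error at line %d: bad coordinates '%s'-'%s'",
                    i, f[4], f[5]))
    }
    if (!f[7] %in% c("+", "-")) {
      abort(sprintf("GTF parse error at line %d: bad strand '%s'", i, f[7]))
    }
    gene <- stringr::str_match(f[9], "gene_id \"([^\"]+)\"")[, 2]
    tx <- stringr::str_match(f[9], "transcript_id \"([^\"]+)\"")[, 2]
    if (is.na(gene) || is.na(tx)) {
      abort(sprintf("GTF parse error at line %d: missing gene_id or transcript_id attribute", i))
    }
    ri <- ri + 1L
    rows[[ri]] <- tibble(gene_id = gene, transcript_id = tx, chrom = f[1],
                         strand = f[7], start = start1 - 1L, end = end1)
  }
  if (ri == 0L) {
    return(as_annotation(tibble(gene_id = character(), transcript_id = character(),
                                chrom = character(), strand = character(),
                                start = integer(), end = integer())))
  }
  as_annotation(bind_rows(rows[seq_len(ri)]))
}

#' Write an exon annotation as GTF
#'
#' Emits one `exon` feature line per exon, 1-based inclusive coordinates,
#' with `gene_id`/`transcript_id` attributes, matching the dialect
#' [read_gtf()] consumes (round-trip safe).
#'
#' @param annotation a `tx_annotation` tibble.
#' @param path output path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, source = "splicemapr") {
  ann <- as_annotation(annotation)
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ann$chrom, source, ann$start + 1L, ann$end, ann$strand,
    ann$gene_id, ann$transcript_id)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Per-transcript summary of an annotation
#'
#' @param annotation a `tx_annotation` tibble.
#' @return tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `n_exons`, `spliced_len`.
#' @export
transcript_summary <- function(annotation) {
  as_annotation(annotation) |>
    group_by(.data$transcript_id) |>
    summarise(gene_id = first(.data$gene_id), chrom = first(.data$chrom),
              strand = first(.data$strand), n_exons = n(),
              spliced_len = sum(.data$end - .data$start), .groups = "drop")
}
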