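# FASTA/FASTQ boundaries (Biostrings) and transcript <-> genome coordinate
# arithmetic.  A genome is a named character vector of chromosome sequences;
# transcript coordinates run 5'->3' along the transcript, so offset 0 of a
# minus-strand transcript is the genomic end of its last exon.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' Quality is a constant string (`"I"`, Phred 40): downstream statistics in
#' this package never consume qualities.
#'
#' @param reads tibble with columns `read_id`, `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$seq,
                           "+",
                           strrep("I", nchar(reads$seq))))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a reads tibble
#'
#' @param path FASTQ file.
#' @return tibble with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

exons_of <- function(annotation, transcript_id) {
  ex <- annotation[annotation$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0) abort(paste0("unknown transcript: ", transcript_id))
  ex[order(ex$start), , drop = FALSE]
}

#' Spliced transcript sequences
#'
#' Concatenates each transcript's exon substrings in genomic order and
#' reverse-complements the result for minus-strand transcripts, i.e. returns
#' the mRNA-sense sequence.
#'
#' @param annotation a `tx_annotation` tibble.
#' @param genome named character vector of chromosome sequences.
#' @param transcript_ids transcripts to extract (default: all).
#' @return named character vector of spliced sequences.
#' @export
transcript_sequence <- function(annotation, genome,
                                transcript_ids = NULL) {
  ann <- as_annotation(annotation)
  ids <- transcript_ids %||% unique(ann$transcript_id)
  out <- vapply(ids, function(tx) {
    ex <- exons_of(ann, tx)
    chrom <- ex$chrom[1]
    if (!chrom %in% names(genome)) {
      abort(paste0("chromosome not in genome: ", chrom))
    }
    clen <- nchar(genome[[chrom]])
    if (any(ex$end > clen)) {
      abort(paste0("exon out of chromosome bounds for transcript ", tx))
    }
    s <- paste(substring(genome[[chrom]], ex$start + 1L, ex$end),
               collapse = "")
    if (ex$strand[1] == "-") revcomp(s) else s
  }, character(1))
  setNames(out, ids)
}

# Project one transcript window [t_start, t_start + length) to the genome.
# Internal single-transcript worker; exons must be sorted by start.
project_window <- function(starts, ends, strand, t_start, length) {
  widths <- ends - starts
  splen <- sum(widths)
  if (t_start < 0 || length < 1 || t_start + length > splen) {
    abort("projection window out of transcript range")
  }
  # A spliced window of a minus-strand transcript is the mirror window of the
  # plus orientation; blocks come out in ascending genomic order either way.
  if (strand == "-") {
    u0 <- splen - (t_start + length)
  } else {
    u0 <- t_start
  }
  u1 <- u0 + length
  sp_start <- cumsum(c(0L, widths))[seq_along(widths)]
  sp_end <- sp_start + widths
  hit <- which(sp_start < u1 & sp_end > u0)
  bs <- starts[hit] + pmax(u0 - sp_start[hit], 0L)
  be <- starts[hit] + pmin(u1 - sp_start[hit], widths[hit])
  list(block_start = as.integer(bs), block_end = as.integer(be))
}

blocks_to_cigar <- function(block_start, block_end) {
  m <- block_end - block_start
  if (length(m) == 1) return(paste0(m, "M"))
  gaps <- block_start[-1] - block_end[-length(block_end)]
  paste0(paste0(m[-length(m)], "M", gaps, "N", collapse = ""),
         m[length(m)], "M")
}

#' Project transcript windows to genomic spliced alignments
#'
#' Maps windows given in transcript coordinates onto the genome as
#' M/N CIGAR alignments: M runs for exonic blocks, N for skipped introns.
#' For minus-strand transcripts the blocks are emitted in ascending genomic
#' order and the alignment strand is `-` (SAM convention).
#'
#' @param annotation a `tx_annotation` tibble.
#' @param transcript_id single transcript id.
#' @param t_start integer vector of 0-based transcript offsets.
#' @param length integer vector (recycled) of window lengths.
#' @return tibble with one row per window: `chrom`, `pos` (0-based leftmost),
#'   `strand`, `cigar`.
#' @export
#' @examples
#' ann <- as_annotation(tibble::tibble(
#'   gene_id = "G", transcript_id = "T", chrom = "chr1", strand = "+",
#'   start = c(100L, 300L), end = c(150L, 400L)))
#' project_to_genome(ann, "T", 40, 75)  # 10M150N65M at pos 140
project_to_genome <- function(annotation, transcript_id, t_start, length) {
  ann <- as_annotation(annotation)
  ex <- exons_of(ann, transcript_id)
  nw <- max(length(t_start), length(length))
  t_start <- as.integer(rep_len(t_start, nw))
  length <- as.integer(rep_len(length, nw))
  pos <- integer(nw)
  cigar <- character(nw)
  for (i in seq_len(nw)) {
    b <- project_window(ex$start, ex$end, ex$strand[1], t_start[i], length[i])
    pos[i] <- b$block_start[1]
    cigar[i] <- blocks_to_cigar(b$block_start, b$block_end)
  }
  tibble(chrom = rep(ex$chrom[1], nw), pos = pos,
         strand = rep(ex$strand[1], nw), cigar = cigar)
}
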