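# Plain-text SAM IO for the package's alignment tibbles.
#
# An alignments tibble has one row per alignment record: read_id, mapped,
# chrom, pos (0-based), strand, cigar, nm, n_locations, secondary, and
# optionally seq (read-orientation sequence).  SAM is 1-based; strand '-'
# sets flag 16 and stores SEQ reverse-complemented, unmapped records carry
# flag 4, non-primary records in multiple-reporting mode carry flag 256.
# NM:i holds the substitution count, NH:i the number of equally-best
# placements (also written on records dropped for mapping ambiguity).

empty_alignments <- function() {
  tibble(read_id = character(), mapped = logical(), chrom = character(),
         pos = integer(), strand = character(), cigar = character(),
         nm = integer(), n_locations = integer(), secondary = logical(),
         seq = character())
}

normalize_alignments <- function(aln) {
  aln <- as_tibble(aln)
  if (!"secondary" %in% names(aln)) aln$secondary <- FALSE
  if (!"n_locations" %in% names(aln)) aln$n_locations <- NA_integer_
  if (!"nm" %in% names(aln)) aln$nm <- NA_integer_
  if (!"seq" %in% names(aln)) aln$seq <- NA_character_
  aln$pos <- as.integer(aln$pos)
  aln$nm <- as.integer(aln$nm)
  aln$n_locations <- as.integer(aln$n_locations)
  aln
}

#' Write alignments to a SAM file
#'
#' @param alignments alignments tibble (see package overview); unmapped rows
#'   must have `NA` placement fields.
#' @param refs named integer vector of reference sequence lengths, covering
#'   every chromosome used.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, refs, path) {
  aln <- normalize_alignments(alignments)
  used <- unique(aln$chrom[aln$mapped])
  unknown <- setdiff(used, names(refs))
  if (length(unknown) > 0) {
    abort(paste0("alignment references unknown chromosome(s): ",
                 paste(unknown, collapse = ", ")))
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  flag <- ifelse(aln$mapped, 0L, 4L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L) +
    ifelse(aln$mapped & aln$secondary, 256L, 0L)
  seq_out <- ifelse(is.na(aln$seq), "*",
                    ifelse(aln$mapped & aln$strand == "-",
                           revcomp(aln$seq), aln$seq))
  qual_out <- ifelse(seq_out == "*", "*", strrep("I", nchar(seq_out)))
  body <- paste(aln$read_id, flag,
                ifelse(aln$mapped, aln$chrom, "*"),
                ifelse(aln$mapped, aln$pos + 1L, 0L),
                ifelse(aln$mapped, 255L, 0L),
                ifelse(aln$mapped, aln$cigar, "*"),
                "*", 0L, 0L, seq_out, qual_out,
                sep = "\t")
  tags <- paste0(ifelse(is.na(aln$nm), "", paste0("\tNM:i:", aln$nm)),
                 ifelse(is.na(aln$n_locations), "",
                        paste0("\tNH:i:", aln$n_locations)))
  readr::write_lines(c(header, paste0(body, tags)), path)
  invisible(path)
}

#' Read a SAM file into an alignments tibble
#'
#' Inverse of [write_sam()]: 1-based POS becomes 0-based `pos`, flag 16 the
#' `-` strand (SEQ restored to read orientation), flag 4 an unmapped row,
#' flag 256 a secondary row; `NM`/`NH` tags populate `nm`/`n_locations`.
#'
#' @param path SAM file.
#' @return alignments tibble; the `@SQ` reference lengths are attached as
#'   attribute `refs`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  refs <- setNames(as.integer(stringr::str_match(sq, "LN:([0-9]+)")[, 2]),
                   stringr::str_match(sq, "SN:(\\S+)")[, 2])
  if (length(body) == 0) {
    out <- empty_alignments()
    attr(out, "refs") <- refs
    return(out)
  }
  f <- stringr::str_split_fixed(body, "\t", 12)
  flag <- as.integer(f[, 2])
  mapped <- bitwAnd(flag, 4L) == 0L
  strand <- ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                   NA_character_)
  tagfield <- f[, 12]
  nm <- as.integer(stringr::str_match(tagfield, "NM:i:(-?[0-9]+)")[, 2])
  nh <- as.integer(stringr::str_match(tagfield, "NH:i:(-?[0-9]+)")[, 2])
  seq <- ifelse(f[, 10] == "*", NA_character_,
                ifelse(!is.na(strand) & strand == "-", revcomp(f[, 10]),
                       f[, 10]))
  out <- tibble(read_id = f[, 1],
                mapped = mapped,
                chrom = ifelse(mapped, f[, 3], NA_character_),
                pos = ifelse(mapped, as.integer(f[, 4]) - 1L, NA_integer_),
                strand = strand,
                cigar = ifelse(mapped, f[, 6], NA_character_),
                nm = nm,
                n_locations = nh,
                secondary = mapped & bitwAnd(flag, 256L) > 0L,
                seq = seq)
  attr(out, "refs") <- refs
  out
}
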