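# CIGAR handling and junction profiles.
#
# Junction status, exon span and MOE are all derived from the placement's
# M/N block structure: M and D runs extend the current genomic block, N
# closes a block and opens the next one after the skipped intron, I and S
# consume read bases only.  X and = are normalised to M on input.

CIGAR_OPS <- c("M", "I", "D", "N", "S")

# One str_match_all call over the whole vector; returns per-element lists
# of op/len vectors with X/= normalised to M.
parse_cigar <- function(cigar) {
  bad <- is.na(cigar) | !grepl("^([0-9]+[MIDNSX=])+$", cigar)
  if (any(bad)) {
    abort(paste0("invalid CIGAR: ", cigar[which(bad)[1]]))
  }
  ms <- stringr::str_match_all(cigar, "([0-9]+)([MIDNSX=])")
  lapply(ms, function(m) {
    op <- m[, 3]
    op[op == "X" | op == "="] <- "M"
    list(op = op, len = as.integer(m[, 2]))
  })
}

#' Parse CIGAR strings into operation tables
#'
#' @param cigar character vector of CIGAR strings over `M I D N S X =`
#'   (`X`/`=` are normalised to `M`).
#' @return list (one element per input) of tibbles with columns `op`, `len`.
#' @export
cigar_ops <- function(cigar) {
  lapply(parse_cigar(cigar), function(x) tibble(op = x$op, len = x$len))
}

#' Read length implied by a CIGAR
#'
#' Sum of M, I and S operation lengths (the bases the read contributes).
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector.
#' @export
cigar_read_length <- function(cigar) {
  vapply(parse_cigar(cigar), function(x) {
    sum(x$len[x$op %in% c("M", "I", "S")])
  }, integer(1))
}

#' Genomic blocks of spliced alignments
#'
#' @param pos integer vector of 0-based leftmost positions.
#' @param cigar character vector of CIGAR strings.
#' @return list of two-column integer matrices (`start`, `end`, half-open),
#'   one block per row.
#' @export
cigar_blocks <- function(pos, cigar) {
  opsl <- parse_cigar(cigar)
  purrr::map2(as.integer(pos), opsl, function(p, x) {
    nop <- length(x$op)
    if (x$op[1] == "N" || x$op[nop] == "N") {
      abort("CIGAR must not start or end with N")
    }
    bs <- integer(0); be <- integer(0)
    cur_start <- p; cur <- p
    open <- FALSE
    for (i in seq_len(nop)) {
      op <- x$op[i]; len <- x$len[i]
      if (op == "M" || op == "D") {
        if (!open) { cur_start <- cur; open <- TRUE }
        cur <- cur + len
      } else if (op == "N") {
        if (open) { bs <- c(bs, cur_start); be <- c(be, cur); open <- FALSE }
        cur <- cur + len
      }
      # I and S consume read only
    }
    if (open) { bs <- c(bs, cur_start); be <- c(be, cur) }
    cbind(start = bs, end = be)
  })
}

blocks_key <- function(blocks) {
  vapply(blocks, function(b) {
    paste(paste0(b[, 1], "-", b[, 2]), collapse = ",")
  }, character(1))
}

#' Junction profile of spliced alignments
#'
#' Derives, per alignment, the ordered genomic blocks, the exon span (block
#' count), junction status (span of at least 2), and the MOE — the minimum
#' overlap with an exon, `min(first block length, last block length)` —
#' defined only for junction alignments.
#'
#' @param pos integer vector of 0-based leftmost positions.
#' @param cigar character vector of CIGAR strings.
#' @return tibble with columns `pos`, `cigar`, `blocks` (canonical
#'   `"start-end,..."` string), `exon_span`, `is_junction`, `moe` (`NA` for
#'   single-block alignments), `n_introns`, `intron_lens` (comma string).
#' @export
#' @examples
#' profile_from_cigar(1000, "30M100N45M")  # exon_span 2, moe 30
profile_from_cigar <- function(pos, cigar) {
  bl <- cigar_blocks(pos, cigar)
  span <- vapply(bl, nrow, integer(1))
  firstw <- vapply(bl, function(b) b[1, 2] - b[1, 1], integer(1))
  lastw <- vapply(bl, function(b) b[nrow(b), 2] - b[nrow(b), 1], integer(1))
  introns <- vapply(bl, function(b) {
    if (nrow(b) < 2) return("")
    paste(b[-1, 1] - b[-nrow(b), 2], collapse = ",")
  }, character(1))
  tibble(pos = as.integer(pos), cigar = cigar,
         blocks = blocks_key(bl),
         exon_span = span,
         is_junction = span >= 2L,
         moe = ifelse(span >= 2L, pmin(firstw, lastw), NA_integer_),
         n_introns = span - 1L,
         intron_lens = introns)
}
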