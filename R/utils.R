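#' @keywords internal
"_PACKAGE"

#' @useDynLib splicemapr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols n distinct across
#'   row_number first slice pull rename count if_else
#' @importFrom stats setNames rbinom runif
NULL

# Derive a stage-specific RNG seed from the master seed so that, e.g., adding
# reads never perturbs genome construction.  Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483629L + 1)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Small vectorised reverse complement used on individual reads; whole-sequence
#' work at the FASTA boundary goes through Biostrings.
#'
#' @param x character vector of DNA strings (ACGTN, case-insensitive).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute exactly `k` positions of `s` with a different base each.
mutate_bases <- function(s, k) {
  if (k == 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(v), k)
  for (p in pos) {
    v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
  }
  paste(v, collapse = "")
}

#' All two-block splits of a read and their minimum overlap with an exon
#'
#' Enumerates every way an `read_length`-base read can straddle a single
#' junction (left block of `s` bases, right block of `read_length - s`,
#' both at least 1) and returns the MOE `min(s, read_length - s)` of each.
#'
#' @param read_length read length in bases (default 75).
#' @return tibble with columns `left`, `right`, `moe`, one row per split.
#' @export
#' @examples
#' range(enumerate_moe(75)$moe)  # 1 and 37
enumerate_moe <- function(read_length = 75) {
  stopifnot(read_length >= 2)
  left <- seq_len(read_length - 1)
  tibble(left = left, right = read_length - left,
         moe = pmin(left, read_length - left))
}

write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, quote = "none", escape = "none", eol = "\n",
                   progress = FALSE)
}
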