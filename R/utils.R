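#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @keywords internal
is_dna <- function(x) {
  nzchar(x) & !is.na(x) & grepl("^[ACGT]+$", x)
}

#' @keywords internal
assert_dna <- function(x, what = "sequence") {
  bad <- !is_dna(x)
  if (any(bad)) {
    stop(sprintf("%s must be non-empty A/C/G/T strings (offending value: %s)",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @keywords internal
find_stop_codons <- function(seq, starts) {
  # starts: 1-based codon start positions to inspect; returns starts that are stops
  keep <- starts >= 1L & (starts + 2L) <= nchar(seq)
  starts <- starts[keep]
  if (length(starts) == 0) return(integer(0))
  codons <- substring(seq, starts, starts + 2L)
  starts[codons %in% STOP_CODONS]
}

#' Random DNA sequences
#'
#' Uniform random A/C/G/T strings; used to synthesise candidate guide pools
#' and barcode keys for simulations.
#'
#' @param n Number of sequences.
#' @param len Length of each sequence.
#' @return Character vector of `n` sequences.
#' @export
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
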