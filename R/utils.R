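#' @useDynLib mitorearr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois runif setNames
#' @importFrom utils head tail read.delim write.table
NULL

# IUPAC alphabet accepted in sequences
IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented according to the standard table.
#'
#' @param seq A single DNA string.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Sample a random DNA sequence
#'
#' @param n Length in bp.
#' @param base_probs Named numeric vector of probabilities for A, T, G, C
#'   (normalized internally).
#' @return A character scalar of length-`n` DNA.
#' @export
random_dna <- function(n, base_probs = c(A = 0.25, T = 0.25, G = 0.25, C = 0.25)) {
  stopifnot(n >= 0)
  if (n == 0L) return("")
  p <- base_probs[c("A", "T", "G", "C")]
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = p / sum(p)),
        collapse = "")
}

# split a string into a character vector of single characters
chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# substring on a circular sequence, 1-based inclusive; start > end wraps
# through the origin
circular_substr <- function(seq, start, end) {
  L <- nchar(seq)
  stopifnot(start >= 1L, start <= L, end >= 1L, end <= L)
  if (start <= end) substr(seq, start, end)
  else paste0(substr(seq, start, L), substr(seq, 1L, end))
}

# span length of a (possibly origin-wrapping) interval on a circle of size L
span_length <- function(start, end, wraps_origin, L) {
  ifelse(wraps_origin, (L - start + 1L) + end, end - start + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
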