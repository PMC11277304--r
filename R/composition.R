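#' Base composition and strand skews
#'
#' Frequencies are computed over unambiguous A/C/G/T only; ambiguity
#' codes are counted separately.  Strand skews follow the standard
#' definitions AT skew = (A - T)/(A + T) and GC skew = (G - C)/(G + C).
#' When a denominator is zero the skew is reported as 0 with the
#' `undefined_skew` flag set.
#'
#' @param seq A non-empty DNA string.
#' @return An object of class `base_composition`: frequencies `freqA`,
#'   `freqT`, `freqG`, `freqC`, ambiguous-base count `n_ambiguous`,
#'   `at_skew`, `gc_skew`, and `undefined_skew`.
#' @export
base_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  cc <- table(factor(chars(toupper(seq)), levels = IUPAC_DNA))
  a <- cc[["A"]]; t <- cc[["T"]]; g <- cc[["G"]]; c <- cc[["C"]]
  tot <- a + t + g + c
  if (tot == 0L) stop("sequence has no unambiguous bases")
  undef <- (a + t) == 0L || (g + c) == 0L
  structure(list(
    freqA = a / tot, freqT = t / tot, freqG = g / tot, freqC = c / tot,
    n_ambiguous = nchar(seq) - tot,
    at_skew = if ((a + t) > 0) (a - t) / (a + t) else 0,
    gc_skew = if ((g + c) > 0) (g - c) / (g + c) else 0,
    undefined_skew = undef),
    class = "base_composition")
}

#' AT skew from base frequencies
#' @param freqA,freqT Frequencies (or counts) of A and T.
#' @return `(A - T)/(A + T)`, or 0 when `A + T == 0`.
#' @export
at_skew <- function(freqA, freqT) {
  ifelse(freqA + freqT > 0, (freqA - freqT) / (freqA + freqT), 0)
}

#' GC skew from base frequencies
#' @param freqG,freqC Frequencies (or counts) of G and C.
#' @return `(G - C)/(G + C)`, or 0 when `G + C == 0`.
#' @export
gc_skew <- function(freqG, freqC) {
  ifelse(freqG + freqC > 0, (freqG - freqC) / (freqG + freqC), 0)
}

#' @export
print.base_composition <- function(x, ...) {
  cat(sprintf(
    "<base_composition> A %.1f%%  T %.1f%%  G %.1f%%  C %.1f%%  AT-skew %.2f  GC-skew %.2f\n",
    100 * x$freqA, 100 * x$freqT, 100 * x$freqG, 100 * x$freqC,
    x$at_skew, x$gc_skew))
  invisible(x)
}
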