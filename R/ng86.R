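# Nei-Gojobori (1986) nonsynonymous divergence under the invertebrate
# mitochondrial genetic code (translation table 5), with Jukes-Cantor
# correction.  Site fractions and pathway averaging are computed by
# exhaustive enumeration per codon, memoized across calls.

.ng86_env <- new.env(parent = emptyenv())

#' The invertebrate mitochondrial genetic code
#' @return Named character vector mapping the 64 codons to amino-acid
#'   letters, `"*"` for stops (translation table 5).
#' @export
invertebrate_mt_code <- function() {
  if (is.null(.ng86_env$code))
    .ng86_env$code <- Biostrings::getGeneticCode("5")
  .ng86_env$code
}

#' Translate an in-frame DNA string under the invertebrate mt code
#' @param seq DNA string, length a multiple of 3; codons containing
#'   gaps or ambiguity codes translate to `"X"`.
#' @return Amino-acid string (`*` = stop).
#' @export
translate_mt <- function(seq) {
  code <- invertebrate_mt_code()
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return("")
  cods <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- code[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# per-codon expected (synonymous, nonsynonymous) site counts; changes to
# stop codons are excluded from the per-site denominator; a site whose
# every change creates a stop counts as nonsynonymous
.codon_sites <- function(codon) {
  key <- paste0("S", codon)
  hit <- .ng86_env[[key]]
  if (!is.null(hit)) return(hit)
  code <- invertebrate_mt_code()
  aa <- code[[codon]]
  if (aa == "*") return(NULL)
  bases <- c("A", "C", "G", "T")
  cs <- chars(codon)
  syn <- 0
  for (pos in 1:3) {
    ns <- 0L; nn <- 0L
    for (b in setdiff(bases, cs[pos])) {
      alt <- cs; alt[pos] <- b
      aa2 <- code[[paste(alt, collapse = "")]]
      if (aa2 == "*") next
      if (aa2 == aa) ns <- ns + 1L else nn <- nn + 1L
    }
    if (ns + nn > 0L) syn <- syn + ns / (ns + nn)
  }
  out <- c(syn = syn, nonsyn = 3 - syn)
  assign(key, out, envir = .ng86_env)
  out
}

# pathway-averaged (synonymous, nonsynonymous) difference counts between
# two codons; pathways through stop codons are excluded; NULL when no
# valid pathway exists or an endpoint is a stop codon
.codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  key <- paste0("D", c1, c2)
  hit <- .ng86_env[[key]]
  if (!is.null(hit)) return(if (identical(hit, "none")) NULL else hit)
  code <- invertebrate_mt_code()
  if (code[[c1]] == "*" || code[[c2]] == "*") return(NULL)
  a <- chars(c1); b <- chars(c2)
  dpos <- which(a != b)
  perms <- .permutations(dpos)
  tot <- c(syn = 0, nonsyn = 0); nvalid <- 0L
  for (p in seq_len(nrow(perms))) {
    cur <- a; path_syn <- 0; path_non <- 0; ok <- TRUE
    for (pos in perms[p, ]) {
      prev_aa <- code[[paste(cur, collapse = "")]]
      cur[pos] <- b[pos]
      nxt <- paste(cur, collapse = "")
      nxt_aa <- code[[nxt]]
      if (nxt_aa == "*" && nxt != c2) { ok <- FALSE; break }
      if (nxt_aa == "*") { ok <- FALSE; break }  # endpoint stop guarded above
      if (nxt_aa == prev_aa) path_syn <- path_syn + 1
      else path_non <- path_non + 1
    }
    if (ok) {
      tot <- tot + c(syn = path_syn, nonsyn = path_non)
      nvalid <- nvalid + 1L
    }
  }
  out <- if (nvalid == 0L) NULL else tot / nvalid
  assign(key, if (is.null(out)) "none" else out, envir = .ng86_env)
  out
}

.permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Nei-Gojobori (1986) nonsynonymous divergence between two aligned
#' coding sequences
#'
#' Expected synonymous/nonsynonymous site counts are enumerated per
#' codon under the invertebrate mitochondrial code and averaged between
#' the two sequences; multi-substitution codons average their
#' differences over all minimal mutational pathways that avoid stop
#' codons.  Codons containing gaps (`-`) or ambiguity codes, stop
#' codons, and codon pairs whose every pathway passes through a stop are
#' skipped and counted in `n_skipped`.  The proportion
#' `pN = nonsyn_diffs / nonsyn_sites` is Jukes-Cantor corrected to
#' `Ka = -(3/4) log(1 - (4/3) pN)`.
#'
#' @param seq1,seq2 In-frame DNA strings of equal length, a multiple
#'   of 3; gaps allowed as `-`.
#' @return An object of class `ka_result`.
#' @export
ng86_ka <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  n <- nchar(seq1)
  if (n != nchar(seq2)) stop("sequences must be the same length")
  if (n %% 3L != 0L) stop("length must be a multiple of 3")
  starts <- seq(1L, n, 3L)
  cods1 <- substring(seq1, starts, starts + 2L)
  cods2 <- substring(seq2, starts, starts + 2L)
  acgt <- function(x) !grepl("[^ACGT]", x)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0L; skipped <- 0L
  for (i in seq_along(cods1)) {
    c1 <- cods1[i]; c2 <- cods2[i]
    if (!acgt(c1) || !acgt(c2)) { skipped <- skipped + 1L; next }
    s1 <- .codon_sites(c1); s2 <- .codon_sites(c2)
    if (is.null(s1) || is.null(s2)) { skipped <- skipped + 1L; next }
    d <- .codon_diffs(c1, c2)
    if (is.null(d)) { skipped <- skipped + 1L; next }
    S <- S + (s1[["syn"]] + s2[["syn"]]) / 2
    N <- N + (s1[["nonsyn"]] + s2[["nonsyn"]]) / 2
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["nonsyn"]]
    used <- used + 1L
  }
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  saturated <- pN >= 0.75
  ka <- if (saturated) NA_real_ else -0.75 * log(1 - (4 / 3) * pN)
  structure(list(
    syn_sites = S, nonsyn_sites = N,
    syn_diffs = Sd, nonsyn_diffs = Nd,
    pN = pN, pS = pS, Ka = ka, saturated = saturated,
    n_codons = used, n_skipped = skipped),
    class = "ka_result")
}

#' @export
print.ka_result <- function(x, ...) {
  cat(sprintf(
    "<ka_result> Ka = %s  (pN = %.5f over %.1f nonsyn sites, %d codons, %d skipped)\n",
    if (x$saturated) "saturated" else sprintf("%.5f", x$Ka),
    x$pN, x$nonsyn_sites, x$n_codons, x$n_skipped))
  invisible(x)
}

# align two coding sequences as codons via translated-protein global
# alignment (match +1, mismatch -1, gap -2) back-threaded to nucleotides
.codon_align <- function(seq1, seq2) {
  p1 <- translate_mt(seq1); p2 <- translate_mt(seq2)
  if (identical(p1, p2) && nchar(seq1) == nchar(seq2))
    return(list(a = seq1, b = seq2))
  alpha <- c(Biostrings::AA_STANDARD, "X", "*")
  m <- matrix(-1, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = m, gapOpening = 0, gapExtension = 2,
    type = "global")
  a1 <- chars(as.character(Biostrings::alignedPattern(pa)))
  a2 <- chars(as.character(Biostrings::alignedSubject(pa)))
  i <- 0L; j <- 0L
  out1 <- character(length(a1)); out2 <- character(length(a2))
  for (k in seq_along(a1)) {
    if (a1[k] != "-") { out1[k] <- substr(seq1, 3L * i + 1L, 3L * i + 3L); i <- i + 1L }
    else out1[k] <- "---"
    if (a2[k] != "-") { out2[k] <- substr(seq2, 3L * j + 1L, 3L * j + 3L); j <- j + 1L }
    else out2[k] <- "---"
  }
  list(a = paste(out1, collapse = ""), b = paste(out2, collapse = ""))
}

# strip a terminal stop codon (complete or the common incomplete T/TA)
.strip_stop <- function(seq) {
  n <- nchar(seq)
  r <- n %% 3L
  if (r > 0L) seq <- substr(seq, 1L, n - r)  # drop incomplete tail
  n <- nchar(seq)
  if (n >= 3L) {
    last <- substr(seq, n - 2L, n)
    code <- invertebrate_mt_code()
    if (!is.na(code[last]) && code[[last]] == "*")
      seq <- substr(seq, 1L, n - 3L)
  }
  seq
}

#' Concatenated and per-gene Ka between two annotated mitogenomes
#'
#' For each of the 13 protein-coding genes shared by the two records the
#' coding sequences are extracted, terminal stop codons stripped,
#' codon-aligned via their translations, and scored with [ng86_ka()];
#' a concatenated estimate over all shared genes is also returned.
#' Genes missing from either record are skipped with a warning and
#' listed in the result.
#'
#' @param query,reference [mitogenome_record()] objects annotated with
#'   protein-coding genes.
#' @return A list with `concatenated` (a `ka_result`), `per_gene`
#'   (named list of `ka_result`), and `skipped_genes`.
#' @export
ka_against_reference <- function(query, reference) {
  genes <- CANONICAL_PCGS
  per_gene <- list(); skipped <- character()
  cat_a <- character(); cat_b <- character()
  for (g in genes) {
    in_q <- g %in% query$features$name
    in_r <- g %in% reference$features$name
    if (!in_q || !in_r) {
      warning("gene ", g, " missing from ",
              if (!in_q) "query" else "reference", "; skipped")
      skipped <- c(skipped, g)
      next
    }
    sq <- .strip_stop(extract_feature_seq(query, g))
    sr <- .strip_stop(extract_feature_seq(reference, g))
    al <- .codon_align(sq, sr)
    per_gene[[g]] <- ng86_ka(al$a, al$b)
    cat_a <- c(cat_a, al$a); cat_b <- c(cat_b, al$b)
  }
  if (!length(per_gene)) stop("no shared protein-coding genes")
  list(concatenated = ng86_ka(paste(cat_a, collapse = ""),
                              paste(cat_b, collapse = "")),
       per_gene = per_gene,
       skipped_genes = skipped)
}
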