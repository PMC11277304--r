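# Circular signed gene orders and single-event rearrangement
# classification relative to the ancestral insect arrangement.

#' Construct a circular signed gene order
#'
#' @param name Character vector of canonical gene tokens, in circular
#'   order along the J strand.
#' @param strand `"J"`/`"N"` per gene.
#' @param origin_token Gene fixing the rotation for serialization;
#'   defaults to `trnI` when present, else the first gene.
#' @return An object of class `gene_order`.
#' @export
gene_order <- function(name, strand, origin_token = NULL) {
  stopifnot(length(name) == length(strand))
  if (anyDuplicated(name))
    stop("duplicate gene in order: ", name[duplicated(name)][1])
  anchor <- origin_token %||% if ("trnI" %in% name) "trnI" else name[1]
  ord <- structure(list(name = as.character(name),
                        strand = as.character(strand),
                        origin_token = anchor),
                   class = "gene_order")
  rotate_order(ord, anchor)
}

#' Rotate a gene order so a given gene comes first
#' @param order A `gene_order`.
#' @param anchor Gene token to rotate to the front.
#' @return The rotated `gene_order`.
#' @export
rotate_order <- function(order, anchor) {
  i <- match(anchor, order$name)
  if (is.na(i)) stop("anchor gene ", anchor, " not in order")
  idx <- c(i:length(order$name), seq_len(i - 1L))
  order$name <- order$name[idx]
  order$strand <- order$strand[idx]
  order$origin_token <- anchor
  order
}

#' Rotation-invariant equality of two circular gene orders
#' @param a,b `gene_order` objects.
#' @return `TRUE` iff one is a rotation of the other with identical
#'   strands.
#' @export
orders_equal <- function(a, b) {
  n <- length(a$name)
  if (n != length(b$name)) return(FALSE)
  if (n == 0L) return(TRUE)
  for (i in seq_len(n)) {
    idx <- c(i:n, seq_len(i - 1L))
    if (identical(b$name[idx], a$name) &&
        identical(b$strand[idx], a$strand)) return(TRUE)
  }
  FALSE
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> ", format_gene_order(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a gene order to its string form
#'
#' Comma-separated tokens, N-strand genes prefixed with `-`, rotation
#' anchored at the order's origin token.
#'
#' @param order A `gene_order`.
#' @return A character scalar, e.g. `"trnI,-trnQ,trnM,ND2,..."`.
#' @export
format_gene_order <- function(order) {
  paste(ifelse(order$strand == "N", paste0("-", order$name), order$name),
        collapse = ",")
}

#' Parse the string form of a gene order
#' @param text String as produced by [format_gene_order()].
#' @return A `gene_order`.
#' @export
parse_gene_order <- function(text) {
  toks <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  strand <- ifelse(startsWith(toks, "-"), "N", "J")
  gene_order(sub("^-", "", toks), strand)
}

#' Extract the circular gene order of an annotated record
#'
#' Features in circular J-strand coordinate order; the control region is
#' included as a token; non-canonical features are dropped.
#'
#' @param record A [mitogenome_record()].
#' @return A `gene_order`.
#' @export
extract_gene_order <- function(record) {
  f <- record$features
  f <- f[f$name %in% CANONICAL_GENES, , drop = FALSE]
  if (!nrow(f)) stop("record has no canonical features")
  f <- f[order(f$start), , drop = FALSE]
  gene_order(f$name, f$strand)
}

#' The ancestral insect (pancrustacean) mitogenome arrangement
#'
#' The hard-coded 37-gene + control-region order shared by most insects
#' (the *Drosophila*-like plesiomorphic arrangement), with strands; its
#' ND2 neighborhood reads ND2, trnW, trnC, trnY.
#'
#' @return A `gene_order` of 38 tokens anchored at `trnI`.
#' @export
ancestral_insect_order <- function() {
  spec <- c(
    "trnI" = "J", "trnQ" = "N", "trnM" = "J", "ND2" = "J", "trnW" = "J",
    "trnC" = "N", "trnY" = "N", "COX1" = "J", "trnL2" = "J", "COX2" = "J",
    "trnK" = "J", "trnD" = "J", "ATP8" = "J", "ATP6" = "J", "COX3" = "J",
    "trnG" = "J", "ND3" = "J", "trnA" = "J", "trnR" = "J", "trnN" = "J",
    "trnS1" = "J", "trnE" = "J", "trnF" = "N", "ND5" = "N", "trnH" = "N",
    "ND4" = "N", "ND4L" = "N", "trnT" = "J", "trnP" = "N", "ND6" = "J",
    "CYTB" = "J", "trnS2" = "J", "ND1" = "N", "trnL1" = "N", "rrnL" = "N",
    "trnV" = "N", "rrnS" = "N", "control_region" = "J")
  gene_order(names(spec), unname(spec))
}

#' Classify the rearrangement between two circular gene orders
#'
#' Orders are restricted to their shared gene set, breakpoints (observed
#' adjacencies absent from the reference) are counted circularly, and
#' the difference is classified as one single event where possible:
#' `identical`, `adjacent_swap` (two neighboring genes exchanged),
#' `block_transposition` (one contiguous block moved), `inversion` (one
#' block reversed with strands flipped), else `complex`.  Strands are
#' carried per gene but not used for breakpoint counting, so a
#' same-strand transposition of genes that sit on opposite strands (the
#' usual tRNA case) classifies as an unsigned swap.
#'
#' @param observed,reference `gene_order` objects over the same gene set
#'   (genes missing from one are dropped and recorded).
#' @return An object of class `rearrangement_call` with `status`,
#'   `affected_genes`, `window` (flanking genes), `breakpoint_count`,
#'   and `dropped_genes`.
#' @export
compare_orders <- function(observed, reference) {
  shared <- intersect(observed$name, reference$name)
  if (!length(shared)) stop("orders share no genes")
  dropped <- setdiff(union(observed$name, reference$name), shared)
  obs <- .restrict_order(observed, shared)
  ref <- .restrict_order(reference, shared)
  n <- length(shared)

  adj <- function(o) {
    nx <- c(o$name[-1], o$name[1])
    paste(o$name, nx, sep = ">")
  }
  bp <- sum(!(adj(obs) %in% adj(ref)))

  status <- "complex"; affected <- character(); window <- c(NA, NA)
  if (bp == 0L) {
    status <- "identical"
  } else {
    hit <- .find_single_event(obs, ref)
    if (!is.null(hit)) {
      status <- hit$status
      affected <- hit$affected
    }
    window <- .diff_window(obs, ref)
  }
  structure(list(status = status,
                 affected_genes = affected,
                 window = window,
                 breakpoint_count = bp,
                 dropped_genes = dropped),
            class = "rearrangement_call")
}

.restrict_order <- function(order, genes) {
  keep <- order$name %in% genes
  gene_order(order$name[keep], order$strand[keep],
             origin_token = order$name[keep][1])
}

# search all single-event explanations: adjacent swap, block
# transposition, block inversion (applied to the reference, compared to
# the observed order rotation-invariantly)
.find_single_event <- function(obs, ref) {
  n <- length(ref$name)
  mk <- function(name, strand) list(name = name, strand = strand)
  eq <- function(cand) {
    co <- gene_order(cand$name, cand$strand, origin_token = cand$name[1])
    orders_equal(co, obs)
  }
  idx_wrap <- function(i) ((i - 1L) %% n) + 1L
  # adjacent swaps (circular)
  for (i in seq_len(n)) {
    j <- idx_wrap(i + 1L)
    nm <- ref$name; st <- ref$strand
    nm[c(i, j)] <- nm[c(j, i)]; st[c(i, j)] <- st[c(j, i)]
    if (eq(mk(nm, st)))
      return(list(status = "adjacent_swap",
                  affected = ref$name[c(i, j)]))
  }
  # block transpositions: move block [i, i+len-1] after position k
  for (i in seq_len(n)) for (len in seq_len(n - 2L)) {
    block <- idx_wrap(seq(i, i + len - 1L))
    rest <- setdiff(seq_len(n), block)
    if (length(rest) < 1L) next
    for (k in seq_along(rest)) {
      nm <- c(ref$name[rest[seq_len(k)]], ref$name[block],
              ref$name[rest[-seq_len(k)]])
      st <- c(ref$strand[rest[seq_len(k)]], ref$strand[block],
              ref$strand[rest[-seq_len(k)]])
      if (eq(mk(nm, st)))
        return(list(status = "block_transposition",
                    affected = ref$name[block]))
    }
  }
  # block inversions: reverse block and flip strands
  for (i in seq_len(n)) for (len in 2:max(2L, n - 1L)) {
    if (len > n - 1L) next
    block <- idx_wrap(seq(i, i + len - 1L))
    nm <- ref$name; st <- ref$strand
    nm[block] <- rev(ref$name[block])
    st[block] <- rev(ifelse(ref$strand[block] == "J", "N", "J"))
    if (eq(mk(nm, st)))
      return(list(status = "inversion", affected = ref$name[block]))
  }
  NULL
}

# minimal differing window: flanking genes just outside the maximal
# shared prefix/suffix once both orders are rotated to a common anchor
.diff_window <- function(obs, ref) {
  anchor <- intersect(ref$name, obs$name)[1]
  o <- rotate_order(obs, anchor)$name
  r <- rotate_order(ref, anchor)$name
  n <- length(o)
  first <- which(o != r)[1]
  last <- tail(which(o != r), 1)
  left <- if (first > 1L) r[first - 1L] else r[n]
  right <- if (last < n) r[last + 1L] else r[1L]
  c(left, right)
}

#' @export
print.rearrangement_call <- function(x, ...) {
  cat(sprintf("<rearrangement_call> %s", x$status))
  if (length(x$affected_genes))
    cat(": ", paste(x$affected_genes, collapse = ", "), sep = "")
  if (!all(is.na(x$window)))
    cat(sprintf("  [window %s .. %s]", x$window[1], x$window[2]))
  cat(sprintf("  (%d breakpoints)\n", x$breakpoint_count))
  invisible(x)
}
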