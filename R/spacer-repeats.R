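# Intergenic spacer extraction, tandem-repeat decomposition and
# degenerate gene-remnant (pseudogene) detection.

#' Extract the intergenic spacer between two adjacent genes
#'
#' @param record A [mitogenome_record()].
#' @param left,right Canonical gene tokens; must be circularly adjacent
#'   in the record with a positive gap.
#' @return An object of class `spacer_region`: `left_gene`,
#'   `right_gene`, `seq` (J-strand gap sequence), `length`, and genome
#'   coordinates `start`/`end` (1-based inclusive).
#' @export
extract_spacer <- function(record, left, right) {
  jr <- junction_report(record)
  jn <- jr$junctions
  hit <- which(jn$left == left & jn$right == right)
  if (!length(hit))
    stop("genes ", left, " and ", right, " are not adjacent")
  gap <- jn$gap[hit[1]]
  if (gap <= 0L)
    stop("no spacer between ", left, " and ", right,
         " (gap = ", gap, " bp)")
  f <- record$features
  e <- f$end[match(left, f$name)]
  L <- genome_length(record)
  start <- if (e == L) 1L else e + 1L
  end <- ((e + gap - 1L) %% L) + 1L
  structure(list(left_gene = left, right_gene = right,
                 seq = circular_substr(record$sequence, start, end),
                 length = gap, start = start, end = end),
            class = "spacer_region")
}

#' @export
print.spacer_region <- function(x, ...) {
  cat(sprintf("<spacer_region> %s..%s: %d bp (%d..%d)\n", x$left_gene,
              x$right_gene, x$length, x$start, x$end))
  invisible(x)
}

#' Decompose a sequence into tandemly repeated units
#'
#' A tandem-repeat search in the spirit of Tandem Repeats Finder,
#' restricted to gapless copies: candidate periods are scanned
#' exhaustively, a lag-match profile (`seq[i] == seq[i + p]`) is scored
#' (+1 match, -3 mismatch) and its best-scoring contiguous interval
#' found; an interval of length `l` at lag `p` supports a repeat region
#' of `l + p` bp, i.e. `floor((l + p)/p)` full copies plus a trailing
#' partial unit of `(l + p) mod p` bp.  Copies are aligned to a
#' majority-rule consensus and per-copy mismatches recorded.
#' Overlapping candidates are deduplicated best-first; ties break to the
#' smaller period, then the leftmost start.
#'
#' @param seq DNA string.
#' @param min_period,max_period Period search range in bp.
#' @param min_copies Minimum number of full copies (default 2).
#' @param min_score Minimum interval score to report (default 10).
#' @param min_identity Minimum fraction of matching positions in the
#'   lag profile over the interval (default 0.8).
#' @return A list of `tandem_decomposition` objects, best score first
#'   (empty when the sequence is shorter than `2 * min_period` or
#'   nothing passes the thresholds).
#' @export
decompose_tandem <- function(seq, min_period = 10L, max_period = 300L,
                             min_copies = 2L, min_score = 10,
                             min_identity = 0.8) {
  n <- nchar(seq)
  if (n < 2L * min_period) return(list())
  s <- chars(toupper(seq))
  cands <- list()
  for (p in seq.int(min_period, min(max_period, n %/% 2L))) {
    m <- s[seq_len(n - p)] == s[(p + 1L):n]
    sc <- ifelse(m, 1, -3)
    iv <- .max_subarray(sc)
    if (is.null(iv)) next
    len <- iv$end - iv$start + 1L
    # a true tandem's maximal interval may shed edge mismatches, so
    # admit intervals covering most of one period and let boundary
    # refinement recover the clipped copies
    if (len < 0.8 * p) next
    ident <- sum(m[iv$start:iv$end]) / len
    if (iv$score < min_score || ident < min_identity) next
    total <- len + p
    dec <- .build_decomposition(s, p, iv$start, total,
                                total %/% p, iv$score, n)
    if (dec$copy_number < min_copies) next
    tot_mm <- sum(vapply(dec$copy_alignments, `[[`, 0L, "mismatches")) +
      dec$partial_unit_mismatches
    if (1 - tot_mm / (dec$end - dec$start + 1L) < min_identity) next
    cands[[length(cands) + 1L]] <- dec
  }
  if (!length(cands)) return(list())
  ord <- order(-vapply(cands, `[[`, 0, "score"),
               vapply(cands, `[[`, 0L, "period"),
               vapply(cands, `[[`, 0L, "start"))
  cands <- cands[ord]
  kept <- list()
  for (cd in cands) {
    clash <- any(vapply(kept, function(k) {
      ov <- min(cd$end, k$end) - max(cd$start, k$start) + 1L
      ov > 0.5 * (cd$end - cd$start + 1L)
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- cd
  }
  kept
}

# Kadane maximum-scoring subarray; returns NULL for all-negative input
.max_subarray <- function(x) {
  best <- -Inf; cur <- 0; cur_start <- 1L
  b_start <- NA_integer_; b_end <- NA_integer_
  for (i in seq_along(x)) {
    if (cur <= 0) { cur <- x[i]; cur_start <- i } else cur <- cur + x[i]
    if (cur > best) { best <- cur; b_start <- cur_start; b_end <- i }
  }
  if (!is.finite(best) || best <= 0) return(NULL)
  list(score = best, start = b_start, end = b_end)
}

.build_decomposition <- function(s, p, start, total, copies, score, n) {
  end <- min(start + total - 1L, n)
  copies <- (end - start + 1L) %/% p
  cons <- .consensus_of(s, start, p, copies)

  # boundary refinement: a point mutation near the region edge breaks
  # the lag profile twice and clips a full copy; re-anchor against the
  # consensus, which a single mutation breaks only once
  # (1) mismatch-tolerant leftward extension re-anchors the copy grid
  lo <- max(1L, start - p + 1L)
  if (start > lo) {
    idx <- (start - 1L):lo
    phase <- ((idx - start) %% p) + 1L
    sc <- ifelse(s[idx] == cons[phase], 1, -3)
    run <- cumsum(sc)
    delta <- if (max(run) > 0) which.max(run) else 0L
    if (delta > 0L) {
      start <- start - delta
      copies <- (end - start + 1L) %/% p
      cons <- .consensus_of(s, start, p, copies)
    }
  }
  # (1b) a mutated leading base can mis-anchor the whole copy grid by
  # a few positions; shift the anchor back to the sequence edge when
  # that yields an extra full copy of acceptable identity
  delta <- (start - 1L) %% p
  if (delta > 0L && delta <= 6L) {
    ns <- start - delta
    copies2 <- (end - ns + 1L) %/% p
    if (copies2 > copies) {
      cons2 <- .consensus_of(s, ns, p, copies2)
      if (mean(s[ns + seq_len(p) - 1L] == cons2) >= 0.8) {
        start <- ns; copies <- copies2; cons <- cons2
      }
    }
  }
  # (2) re-admit clipped full copies at either end
  repeat {
    a2 <- start - p
    if (a2 < 1L) break
    if (mean(s[a2 + seq_len(p) - 1L] == cons) < 0.8) break
    start <- a2; copies <- copies + 1L
  }
  repeat {
    nxt <- start + copies * p
    if (nxt + p - 1L > n) break
    if (mean(s[nxt + seq_len(p) - 1L] == cons) < 0.8) break
    copies <- copies + 1L
  }
  cons <- .consensus_of(s, start, p, copies)
  # (3) trailing partial unit: best mismatch-tolerant consensus prefix
  tail_from <- start + copies * p
  tail_len <- min(p - 1L, n - tail_from + 1L)
  partial <- 0L
  if (tail_len > 0L) {
    idx <- tail_from + seq_len(tail_len) - 1L
    sc <- cumsum(ifelse(s[idx] == cons[seq_len(tail_len)], 1, -3))
    if (max(sc) > 0) partial <- which.max(sc)
  }
  end <- start + copies * p + partial - 1L

  copy_aln <- lapply(seq_len(copies), function(c) {
    cp <- s[start + (c - 1L) * p + seq_len(p) - 1L]
    mm <- which(cp != cons)
    list(copy = c, start = start + (c - 1L) * p,
         mismatch_positions = mm, mismatches = length(mm))
  })
  total_mm <- sum(vapply(copy_aln, `[[`, 0L, "mismatches"))
  partial_mm <- if (partial > 0L)
    sum(s[start + copies * p + seq_len(partial) - 1L] !=
          cons[seq_len(partial)]) else 0L
  total <- end - start + 1L
  score <- (total - total_mm - partial_mm) - 3 * (total_mm + partial_mm)
  structure(list(period = p, copy_number = copies,
                 consensus = paste(cons, collapse = ""),
                 copy_alignments = copy_aln,
                 partial_unit_length = partial,
                 partial_unit_mismatches = partial_mm,
                 start = start, end = end, score = score,
                 coverage_fraction = total / n),
            class = "tandem_decomposition")
}

.consensus_of <- function(s, start, p, copies) {
  mat <- matrix(NA_character_, nrow = copies, ncol = p)
  for (c in seq_len(copies))
    mat[c, ] <- s[start + (c - 1L) * p + seq_len(p) - 1L]
  apply(mat, 2L, function(col)
    names(sort(table(col), decreasing = TRUE))[1])
}

#' @export
print.tandem_decomposition <- function(x, ...) {
  mm <- sum(vapply(x$copy_alignments, `[[`, 0L, "mismatches"))
  cat(sprintf(
    "<tandem_decomposition> period %d bp x %d copies + %d bp partial (%d..%d, %d mismatches, score %g)\n",
    x$period, x$copy_number, x$partial_unit_length, x$start, x$end, mm,
    x$score))
  invisible(x)
}

# trim an alignment's ends to its maximal-scoring core under a
# conservative rescoring (match +1, mismatch -3, gap -4), so maximal
# local alignments do not drift into flanking noise; returns trimmed
# subject coordinates and match statistics, rescored with the original
# scheme (+1/-1/-2)
.trim_alignment <- function(al) {
  ca <- chars(al$a_aln); cb <- chars(al$b_aln)
  gap <- ca == "-" | cb == "-"
  match <- ca == cb & !gap
  core <- .max_subarray(ifelse(match, 1, ifelse(gap, -4, -3)))
  idx <- if (is.null(core)) seq_along(ca) else core$start:core$end
  b_adv <- cumsum(cb != "-")
  b_start <- al$b_start + if (idx[1] > 1L) b_adv[idx[1] - 1L] else 0L
  b_end <- al$b_start + b_adv[idx[length(idx)]] - 1L
  g <- gap[idx]
  n_gap_runs <- sum(g & !c(FALSE, g[-length(g)]))
  list(b_start = b_start, b_end = b_end,
       ncol = length(idx),
       nmatch = sum(match[idx]),
       mism = sum(!match[idx] & !g),
       score = sum(ifelse(match[idx], 1, ifelse(g, -2, -1))) -
         2 * n_gap_runs)
}

#' Scan a spacer for degenerate remnants of intact genes
#'
#' Each library gene and its reverse complement is aligned locally
#' (Smith-Waterman with affine gaps: match +1, mismatch -1, gap open
#' -2, gap extend -2 per base) against the
#' spacer; each maximal alignment is then trimmed to its
#' maximal-scoring core under a conservative rescoring (mismatch -3,
#' gap -4) so hit boundaries do not drift into flanking noise.  After
#' each accepted hit the matched spacer interval is masked and the scan
#' repeated, so multiple non-overlapping remnant copies of the same
#' gene are all reported.  Hits from different genes that overlap on
#' the spacer are resolved greedily best-score-first.
#'
#' @param spacer A `spacer_region` (from [extract_spacer()]) or a plain
#'   DNA string.
#' @param gene_library Named character vector (or named list) of intact
#'   gene sequences, e.g. the record's own tRNAs.
#' @param min_len Minimum hit length on the spacer (default 15).
#' @param min_ident Minimum alignment identity (default 0.8).
#' @param min_score Minimum alignment score (default 15).
#' @return A data.frame of class `remnant_hits` with columns
#'   `source_gene`, `strand` (orientation of the matching source gene
#'   strand), `spacer_offset` (1-based start on the spacer), `length`,
#'   `identity`, `mismatches`, `score`, sorted best-first.
#' @export
scan_remnants <- function(spacer, gene_library, min_len = 15L,
                          min_ident = 0.8, min_score = 15) {
  sp <- if (inherits(spacer, "spacer_region")) spacer$seq else spacer
  sp <- toupper(sp)
  if (!length(gene_library)) stop("empty gene library")
  lib <- vapply(gene_library, as.character, "")
  hits <- list()
  for (g in names(lib)) {
    for (strand in c("J", "N")) {
      q <- if (strand == "J") toupper(lib[[g]]) else revcomp(lib[[g]])
      masked <- sp
      repeat {
        al <- .sw_align_cpp(q, masked, 1, -1, 2, 2)
        if (al$score < min_score) break
        tr <- .trim_alignment(al)
        len <- tr$b_end - tr$b_start + 1L
        ident <- tr$nmatch / tr$ncol
        mism <- tr$mism
        if (len >= min_len && ident >= min_ident && tr$score >= min_score)
          hits[[length(hits) + 1L]] <- data.frame(
            source_gene = g, strand = strand,
            spacer_offset = tr$b_start, length = len,
            identity = ident, mismatches = mism, score = tr$score,
            stringsAsFactors = FALSE)
        # mask the full raw alignment span and rescan for more copies
        substr(masked, al$b_start, al$b_end) <-
          paste(rep("#", al$b_end - al$b_start + 1L), collapse = "")
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(source_gene = character(), strand = character(),
                      spacer_offset = integer(), length = integer(),
                      identity = numeric(), mismatches = integer(),
                      score = numeric())
    class(out) <- c("remnant_hits", "data.frame")
    return(out)
  }
  df <- do.call(rbind, hits)
  df <- df[order(-df$score, df$spacer_offset), , drop = FALSE]
  # greedy non-overlap across genes/strands
  keep <- logical(nrow(df))
  occ <- rep(FALSE, nchar(sp))
  for (i in seq_len(nrow(df))) {
    span <- df$spacer_offset[i]:(df$spacer_offset[i] + df$length[i] - 1L)
    if (!any(occ[span])) { keep[i] <- TRUE; occ[span] <- TRUE }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(-df$score, df$spacer_offset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("remnant_hits", "data.frame")
  df
}

#' Annotate tandem repeat units with their remnant and linker parts
#'
#' Assigns each remnant hit to the repeat copy containing it, partitions
#' each copy into a remnant segment and a linker segment (the part of
#' the unit not covered by the modal remnant interval), and computes the
#' pairwise identity of the linkers across copies.  A hit spanning a
#' copy boundary is flagged and left unassigned.
#'
#' @param decomp A `tandem_decomposition`.
#' @param hits A `remnant_hits` table whose offsets are on the same
#'   sequence the decomposition was computed from.
#' @param seq The decomposed DNA string (needed to cut linker
#'   sequences).
#' @return An object of class `tru_annotation`: per-copy table
#'   (`copies`), `remnant_span` (offset/length of the remnant part
#'   within a unit), `linker_length`, `linker_identity` matrix,
#'   `n_remnant_copies`, `linkers_identical`, and `boundary_hits`.
#' @export
annotate_trus <- function(decomp, hits, seq) {
  p <- decomp$period
  k <- decomp$copy_number
  copy_start <- decomp$start + (seq_len(k) - 1L) * p
  copy_end <- copy_start + p - 1L
  assigned <- rep(NA_integer_, nrow(hits))
  boundary <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h0 <- hits$spacer_offset[i]; h1 <- h0 + hits$length[i] - 1L
    cidx <- which(copy_start <= h0 & h1 <= copy_end)
    if (length(cidx) == 1L) assigned[i] <- cidx
    else if (any(copy_start <= h1 & h0 <= copy_end)) boundary[i] <- TRUE
  }
  # modal remnant interval in unit coordinates
  in_copy <- !is.na(assigned)
  if (any(in_copy)) {
    off_in_unit <- hits$spacer_offset[in_copy] - copy_start[assigned[in_copy]] + 1L
    rem_off <- as.integer(names(sort(table(off_in_unit), decreasing = TRUE))[1])
    rem_len <- as.integer(names(sort(table(hits$length[in_copy]),
                                     decreasing = TRUE))[1])
  } else {
    rem_off <- NA_integer_; rem_len <- 0L
  }
  linker_idx <- if (rem_len > 0L)
    setdiff(seq_len(p), rem_off:(rem_off + rem_len - 1L)) else seq_len(p)
  s <- chars(toupper(seq))
  linkers <- vapply(seq_len(k), function(c)
    paste(s[copy_start[c] - 1L + linker_idx], collapse = ""), "")
  lid <- matrix(1, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- chars(linkers[i]); b <- chars(linkers[j])
    lid[i, j] <- mean(a == b)
  }
  copies <- data.frame(
    copy = seq_len(k), start = copy_start,
    has_remnant = tabulate(assigned[in_copy], nbins = k) > 0L,
    remnant_identity = NA_real_)
  for (i in which(in_copy))
    copies$remnant_identity[assigned[i]] <- hits$identity[i]
  structure(list(copies = copies,
                 remnant_span = c(offset = rem_off, length = rem_len),
                 linker_length = length(linker_idx),
                 linker_identity = lid,
                 n_remnant_copies = sum(copies$has_remnant),
                 linkers_identical = all(lid == 1),
                 boundary_hits = which(boundary)),
            class = "tru_annotation")
}

#' @export
print.tru_annotation <- function(x, ...) {
  cat(sprintf(
    "<tru_annotation> %d/%d copies carry a %d bp remnant; linker %d bp (%s)\n",
    x$n_remnant_copies, nrow(x$copies), x$remnant_span[["length"]],
    x$linker_length,
    if (x$linkers_identical) "identical across copies" else "divergent"))
  invisible(x)
}

#' Remnant hits as genome BED-like coordinates
#'
#' Converts spacer-relative hits to genome coordinates, 0-based
#' half-open (BED convention).
#'
#' @param hits A `remnant_hits` table from [scan_remnants()].
#' @param spacer The `spacer_region` the hits were found in.
#' @param genome_id Sequence name for the first column.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
remnants_to_bed <- function(hits, spacer, genome_id = "genome") {
  g0 <- spacer$start - 1L            # 0-based spacer origin on genome
  data.frame(chrom = genome_id,
             start = g0 + hits$spacer_offset - 1L,
             end = g0 + hits$spacer_offset + hits$length - 1L,
             name = paste0(hits$source_gene, "_remnant"),
             score = hits$score,
             strand = ifelse(hits$strand == "J", "+", "-"))
}
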