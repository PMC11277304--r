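#' Overlap/spacer accounting across all gene junctions
#'
#' For each pair of circularly adjacent features the gap is
#' `start(next) - end(prev) - 1` (with circular wrap-around on circular
#' records): negative values are overlaps, positive values intergenic
#' spacers, zero abutting genes.  Fully nested features are excluded
#' from the junction math with a warning, since the counts assume a
#' linear tiling of the circle.
#'
#' @param record A [mitogenome_record()].
#' @return An object of class `junction_report`: a list with the
#'   per-junction table (`junctions`: left, right, gap), overlap and
#'   spacer counts, overlap length extremes, and the longest spacer with
#'   its flanking genes.
#' @export
junction_report <- function(record) {
  f <- record$features
  L <- genome_length(record)
  if (nrow(f) < 2L) {
    jn <- data.frame(left = character(), right = character(),
                     gap = integer())
    return(.junction_summary(jn))
  }
  # drop fully nested features (span contained in another's span)
  s <- ifelse(f$wraps_origin, f$start, f$start)
  e <- ifelse(f$wraps_origin, f$end + L, f$end)  # unwrap to a line
  keep <- rep(TRUE, nrow(f))
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(f))) {
      if (i != j && keep[j] &&
          s[i] >= s[j] && e[i] <= e[j] &&
          !(s[i] == s[j] && e[i] == e[j] && i < j)) {
        if (s[i] > s[j] || e[i] < e[j]) {
          keep[i] <- FALSE
          warning("feature ", f$name[i],
                  " is nested in ", f$name[j],
                  " and excluded from junction accounting")
        }
      }
    }
  }
  f <- f[keep, , drop = FALSE]
  n <- nrow(f)
  # order by start; an origin-wrapping feature sorts by its start and its
  # junction to the first feature uses its (small) end coordinate
  idx <- order(f$start)
  f <- f[idx, , drop = FALSE]
  nxt <- c(seq_len(n)[-1], 1L)
  gap <- integer(n)
  for (i in seq_len(n)) {
    j <- nxt[i]
    g <- f$start[j] - f$end[i] - 1L
    if (i == n && record$topology == "circular" && !f$wraps_origin[i])
      g <- g + L
    gap[i] <- g
  }
  if (record$topology == "linear") gap <- gap[-n]
  jn <- data.frame(left = f$name[seq_along(gap)],
                   right = f$name[nxt[seq_along(gap)]],
                   gap = gap, stringsAsFactors = FALSE)
  .junction_summary(jn)
}

.junction_summary <- function(jn) {
  ov <- jn[jn$gap < 0L, , drop = FALSE]
  sp <- jn[jn$gap > 0L, , drop = FALSE]
  longest <- if (nrow(sp)) sp[which.max(sp$gap), ] else NULL
  structure(list(
    junctions = jn,
    n_overlaps = nrow(ov),
    n_spacers = nrow(sp),
    overlap_range = if (nrow(ov)) range(-ov$gap) else c(NA_integer_, NA_integer_),
    longest_spacer = if (!is.null(longest))
      list(left = longest$left, right = longest$right,
           length = longest$gap) else NULL),
    class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat(sprintf("<junction_report> %d junctions: %d overlaps", nrow(x$junctions),
              x$n_overlaps))
  if (x$n_overlaps)
    cat(sprintf(" (%d-%d bp)", x$overlap_range[1], x$overlap_range[2]))
  cat(sprintf(", %d spacers", x$n_spacers))
  if (!is.null(x$longest_spacer))
    cat(sprintf(", longest %d bp between %s and %s",
                x$longest_spacer$length, x$longest_spacer$left,
                x$longest_spacer$right))
  cat("\n")
  invisible(x)
}
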