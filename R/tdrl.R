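# Tandem duplication-random loss (TDRL) scenario reconstruction.
#
# A TDRL event duplicates a contiguous block of genes in tandem
# (possibly more than twice) and then deletes all but one copy of each
# redundant gene; the surviving copies read off the derived gene order.
# Copies lost *between* the first and the last retained gene instance
# are expected to leave pseudogene remnants in the intergenic spacer,
# which is the evidence used to rank competing scenarios.

#' Construct a TDRL scenario
#'
#' @param block Character vector: the duplicated contiguous gene block,
#'   in ancestral order (empty for the identity scenario).
#' @param block_start Position of the block's first gene in the
#'   ancestral window.
#' @param copy_count Number of tandem copies produced (>= 2; 0 for the
#'   identity scenario).
#' @param retained Named integer vector: for each block gene, the index
#'   of the copy in which it survives.
#' @return An object of class `tdrl_scenario` with `predicted_order`
#'   left unset (filled by [enumerate_scenarios()] /
#'   [apply_scenario()]).
#' @export
tdrl_scenario <- function(block, block_start, copy_count, retained) {
  if (length(block)) {
    if (!setequal(names(retained), block))
      stop("retained must name every block gene exactly once")
    if (any(retained < 1L | retained > copy_count))
      stop("retained copy index out of range")
  }
  structure(list(block = block, block_start = block_start,
                 copy_count = copy_count,
                 retained = retained,
                 event_count = if (length(block)) 1L else 0L,
                 predicted_order = NULL,
                 predicted_remnants = NULL),
            class = "tdrl_scenario")
}

# expanded tandem array and retention mask for a scenario
.expand_array <- function(scenario) {
  b <- scenario$block
  k <- scenario$copy_count
  gene <- rep(b, times = k)
  copy <- rep(seq_len(k), each = length(b))
  data.frame(gene = gene, copy = copy,
             retained = unname(scenario$retained[gene]) == copy)
}

#' Apply a TDRL scenario to an ancestral gene window
#'
#' Expands the duplicated block into tandem copies, deletes every gene
#' instance not marked retained, and returns the surviving order with
#' the flanking genes unchanged.
#'
#' @param ancestral_window Character vector of genes (linearized local
#'   window; flanks fixed).
#' @param scenario A `tdrl_scenario` whose block is contiguous in the
#'   window.
#' @return Character vector: the derived window.
#' @export
apply_scenario <- function(ancestral_window, scenario) {
  if (!length(scenario$block)) return(ancestral_window)
  b <- scenario$block
  i <- scenario$block_start
  if (!identical(ancestral_window[i:(i + length(b) - 1L)], b))
    stop("scenario block is not contiguous at block_start in the window")
  counts <- table(factor(scenario$retained, levels = seq_len(scenario$copy_count)))
  if (any(tabulate(match(names(scenario$retained), b)) != 1L))
    stop("each block gene must be retained exactly once")
  arr <- .expand_array(scenario)
  surv <- arr$gene[arr$retained]
  c(head(ancestral_window, i - 1L), surv,
    tail(ancestral_window, length(ancestral_window) - i - length(b) + 1L))
}

# remnant prediction: lost instances strictly between the first and the
# last retained instance in the expanded array
.predict_remnants <- function(scenario) {
  if (!length(scenario$block))
    return(data.frame(gene = character(), copy = integer()))
  arr <- .expand_array(scenario)
  kept <- which(arr$retained)
  lo <- min(kept); hi <- max(kept)
  idx <- setdiff(seq(lo, hi), kept)
  data.frame(gene = arr$gene[idx], copy = arr$copy[idx])
}

#' Enumerate TDRL scenarios explaining a derived gene window
#'
#' Exhausts every contiguous duplicated block, copy count from 2 to
#' `max_copies`, and loss pattern (which copy retains each gene), and
#' keeps the scenarios whose predicted order equals the derived window.
#' When the two windows are identical the single empty scenario (no
#' duplication, `event_count` 0) is returned.  Results are sorted by
#' `(event_count, copy_count, block length)`.
#'
#' @param ancestral_window,derived_window Character vectors over the
#'   same gene set (at most ~6 genes; the search is exponential).
#' @param max_copies Maximum tandem copy count to consider.
#' @return List of `tdrl_scenario` objects with `predicted_order` and
#'   `predicted_remnants` filled in.
#' @export
enumerate_scenarios <- function(ancestral_window, derived_window,
                                max_copies = 2L) {
  if (!setequal(ancestral_window, derived_window) ||
      length(ancestral_window) != length(derived_window))
    stop("windows must contain the same gene set")
  if (identical(ancestral_window, derived_window)) {
    s <- tdrl_scenario(character(), NA_integer_, 0L, integer())
    s$predicted_order <- ancestral_window
    s$predicted_remnants <- data.frame(gene = character(), copy = integer())
    return(list(s))
  }
  n <- length(ancestral_window)
  out <- list()
  for (i in seq_len(n)) for (len in 2L:n) {
    if (i + len - 1L > n) next
    block <- ancestral_window[i:(i + len - 1L)]
    for (k in 2L:max_copies) {
      grid <- .loss_patterns(len, k)
      for (r in seq_len(nrow(grid))) {
        retained <- setNames(as.integer(grid[r, ]), block)
        s <- tdrl_scenario(block, i, k, retained)
        pred <- apply_scenario(ancestral_window, s)
        if (identical(pred, derived_window)) {
          s$predicted_order <- pred
          s$predicted_remnants <- .predict_remnants(s)
          out[[length(out) + 1L]] <- s
        }
      }
    }
  }
  if (!length(out)) return(out)
  ord <- order(vapply(out, `[[`, 0L, "event_count"),
               vapply(out, `[[`, 0L, "copy_count"),
               vapply(out, function(s) length(s$block), 0L))
  out[ord]
}

# all assignments of len genes to k copies (k^len rows)
.loss_patterns <- function(len, k) {
  as.matrix(expand.grid(rep(list(seq_len(k)), len)))
}

#' Rank TDRL scenarios by pseudogene remnant evidence
#'
#' Scenarios whose predicted remnants agree with the observed remnant
#' genes (same genes, same counts, same order, ignoring genes never
#' observed as remnants) rank first; within each group scenarios sort
#' by `(copy_count, event_count)`.  Reproducing `k` observed remnants
#' of a gene that is itself retained outside the remnant run requires
#' `copy_count >= k + 2`.
#'
#' @param scenarios A list from [enumerate_scenarios()].
#' @param observed_remnants Character vector of observed remnant genes
#'   in spacer order (e.g. `rep("trnW", 6)`), or a data.frame with a
#'   `gene` column.
#' @return The re-ranked scenario list; each scenario gains a logical
#'   `remnants_match` field.
#' @export
rank_by_remnants <- function(scenarios, observed_remnants) {
  obs <- if (is.data.frame(observed_remnants)) observed_remnants$gene
         else as.character(observed_remnants)
  for (i in seq_along(scenarios)) {
    pred <- scenarios[[i]]$predicted_remnants$gene
    restricted <- pred[pred %in% unique(obs)]
    scenarios[[i]]$remnants_match <-
      length(obs) == 0L && length(restricted) == 0L ||
      identical(restricted, obs)
  }
  if (!length(scenarios)) return(scenarios)
  ord <- order(!vapply(scenarios, `[[`, TRUE, "remnants_match"),
               vapply(scenarios, `[[`, 0L, "copy_count"),
               vapply(scenarios, `[[`, 0L, "event_count"))
  scenarios[ord]
}

#' @export
print.tdrl_scenario <- function(x, ...) {
  if (!length(x$block)) {
    cat("<tdrl_scenario> identity (no duplication)\n")
    return(invisible(x))
  }
  cat(sprintf("<tdrl_scenario> duplicate (%s) x%d; retain %s\n",
              paste(x$block, collapse = "-"), x$copy_count,
              paste(sprintf("%s@%d", names(x$retained), x$retained),
                    collapse = ", ")))
  invisible(x)
}

#' Render a TDRL scenario as a human-readable pathway
#'
#' Four stages: the ancestral window, the expanded tandem array, the
#' array with lost copies struck through, and the derived order.
#'
#' @param ancestral_window Character vector of genes.
#' @param scenario A `tdrl_scenario`.
#' @return Character vector of four lines.
#' @export
render_scenario <- function(ancestral_window, scenario) {
  der <- apply_scenario(ancestral_window, scenario)
  if (!length(scenario$block))
    return(c(paste("ancestral:", paste(ancestral_window, collapse = "-")),
             "event    : none",
             paste("derived  :", paste(der, collapse = "-"))))
  arr <- .expand_array(scenario)
  expanded <- paste(arr$gene, collapse = "-")
  losses <- paste(ifelse(arr$retained, arr$gene,
                         paste0("[", arr$gene, "]")), collapse = "-")
  i <- scenario$block_start
  pre <- head(ancestral_window, i - 1L)
  post <- tail(ancestral_window,
               length(ancestral_window) - i - length(scenario$block) + 1L)
  wrap <- function(mid) paste(c(pre, mid, post), collapse = "-")
  c(paste("ancestral :", paste(ancestral_window, collapse = "-")),
    paste("duplicated:", wrap(expanded)),
    paste("losses    :", wrap(losses)),
    paste("derived   :", paste(der, collapse = "-")))
}
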