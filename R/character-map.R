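# Fitch parsimony mapping of a binary character (e.g. presence of a
# gene-order rearrangement) on a rooted phylogeny, with synapomorphy
# detection.

#' Read a newick tree
#'
#' Thin wrapper around [ape::read.tree()] accepting a file path or a
#' newick string; internal node labels (support values) are kept.
#'
#' @param text Newick string or file path.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(text) {
  tr <- if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    ape::read.tree(text)
  else ape::read.tree(text = paste(text, collapse = ""))
  if (is.null(tr)) stop("malformed newick input")
  if (anyDuplicated(tr$tip.label))
    stop("leaf labels must be unique")
  tr
}

#' Root a tree on a declared outgroup
#'
#' @param tree A `phylo` object.
#' @param outgroup Tip label (or labels) of the outgroup.
#' @return A rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (missing(outgroup) || is.null(outgroup))
    stop("an outgroup must be declared to root the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Fitch parsimony map of a binary character on a rooted tree
#'
#' Runs the two-pass Fitch algorithm on a rooted, bifurcating tree with
#' leaf states 0, 1 or `?` (missing; treated as the full state set).
#' Returns the parsimony score, one optimal assignment of internal
#' states (ties at the root resolve to state 0, and children inherit
#' the parental state whenever it is optimal), the set of edges on
#' which the state changes, and -- when the score is 1 and the single
#' change is a gain of state 1 -- the clade the character is a
#' synapomorphy of.
#'
#' @param tree A rooted bifurcating `phylo` object.
#' @param states Named vector (names = tip labels) with values in
#'   `c("0", "1", "?")` (numeric 0/1 and `NA` also accepted).
#' @return An object of class `character_map`: `leaf_states`,
#'   `min_changes`, `node_states`, `change_edges` (matrix of
#'   parent/child node ids), `is_synapomorphy_of` (character vector of
#'   tip labels, or `NULL`).
#' @export
fitch_map <- function(tree, states) {
  if (is.null(tree$edge)) stop("not a phylo tree")
  tips <- tree$tip.label
  unknown <- setdiff(names(states), tips)
  if (length(unknown))
    stop("state given for unknown leaf: ", paste(unknown, collapse = ", "))
  if (!all(tips %in% names(states)))
    stop("missing state for leaf: ",
         paste(setdiff(tips, names(states)), collapse = ", "))
  st <- as.character(states[tips])
  st[is.na(st)] <- "?"
  if (!all(st %in% c("0", "1", "?")))
    stop("states must be 0, 1 or ?")

  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip))
    sets[[i]] <- if (st[i] == "?") c(0L, 1L) else as.integer(st[i])

  edge <- tree$edge
  children <- split(edge[, 2], edge[, 1])
  # postorder over internal nodes
  post <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  changes <- 0L
  for (nd in post) {
    ch <- children[[as.character(nd)]]
    s <- sets[[ch[1]]]
    for (c2 in ch[-1]) {
      inter <- intersect(s, sets[[c2]])
      if (length(inter)) s <- inter
      else { s <- union(s, sets[[c2]]); changes <- changes + 1L }
    }
    sets[[nd]] <- s
  }
  root <- n_tip + 1L
  node_state <- integer(n_node)
  node_state[root] <- if (0L %in% sets[[root]]) 0L else 1L
  pre <- unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1])
  for (nd in pre) {
    for (ch in children[[as.character(nd)]]) {
      node_state[ch] <- if (node_state[nd] %in% sets[[ch]])
        node_state[nd] else sets[[ch]][1]
    }
  }
  change_edges <- edge[node_state[edge[, 1]] != node_state[edge[, 2]], ,
                       drop = FALSE]
  synapo <- NULL
  if (changes == 1L && nrow(change_edges) == 1L &&
      node_state[change_edges[1, 2]] == 1L) {
    sub <- .tips_below(tree, change_edges[1, 2])
    ones <- tips[st == "1"]
    zeros <- tips[st == "0"]
    if (all(ones %in% sub) && !any(zeros %in% sub)) synapo <- sub
  }
  structure(list(leaf_states = setNames(st, tips),
                 min_changes = changes,
                 node_states = node_state,
                 change_edges = change_edges,
                 is_synapomorphy_of = synapo),
            class = "character_map")
}

.tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  edge <- tree$edge
  out <- character()
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    ch <- edge[edge[, 1] == nd, 2]
    out <- c(out, tree$tip.label[ch[ch <= n_tip]])
    stack <- c(stack, ch[ch > n_tip])
  }
  out
}

#' @export
print.character_map <- function(x, ...) {
  cat(sprintf("<character_map> min_changes = %d", x$min_changes))
  if (!is.null(x$is_synapomorphy_of))
    cat("; synapomorphy of (",
        paste(x$is_synapomorphy_of, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Read leaf states from a two-column TSV
#'
#' Columns `taxon` and `state` (0, 1 or ?).
#'
#' @param file Path or lines of the TSV.
#' @return Named character vector of states.
#' @export
read_leaf_states <- function(file) {
  tab <- read.delim(.tsv_con(file), colClasses = "character")
  if (!all(c("taxon", "state") %in% names(tab)))
    stop("leaf state table needs columns taxon, state")
  setNames(tab$state, tab$taxon)
}
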