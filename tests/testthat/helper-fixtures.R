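# shared fixtures and independent oracles for the test suite

.fixture_env <- new.env(parent = emptyenv())

# memoized study-condition genome (ancestral + planted rearrangement)
get_study <- function(seed = 1L) {
  key <- paste0("study", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- study_genome(seed)
  .fixture_env[[key]]
}

# a tiny hand-built record on a known sequence
toy_record <- function() {
  mitogenome_record(
    "TOY1", "ATGCAAGGTTCCAAGGTACTGACA",
    gene_features(name = c("trnW", "trnC"),
                  gene_class = c("tRNA", "tRNA"),
                  strand = c("J", "N"),
                  start = c(2L, 12L), end = c(7L, 20L)))
}

# exhaustive Fitch oracle: minimum changes over all internal labelings
# (and all resolutions of ? leaves)
oracle_fitch <- function(tree, states) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  edge <- tree$edge
  n_node <- n_tip + tree$Nnode
  st <- as.character(states[tips])
  st[is.na(st)] <- "?"
  free <- c(which(st == "?"), (n_tip + 1L):n_node)
  fixed <- integer(n_node)
  fixed[seq_len(n_tip)][st != "?"] <- as.integer(st[st != "?"])
  best <- Inf
  grid <- expand.grid(rep(list(0:1), length(free)))
  for (r in seq_len(nrow(grid))) {
    lab <- fixed
    lab[free] <- as.integer(grid[r, ])
    best <- min(best, sum(lab[edge[, 1]] != lab[edge[, 2]]))
  }
  best
}

# brute-force single-event rearrangement oracle: classify an observed
# circular order by membership in the sets of all single-event
# derivatives of the reference
oracle_single_event <- function(obs, ref) {
  n <- length(ref$name)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  candidates <- function(kind) {
    out <- list()
    if (kind == "swap") {
      for (i in seq_len(n)) {
        j <- wrap(i + 1L)
        nm <- ref$name; stn <- ref$strand
        nm[c(i, j)] <- nm[c(j, i)]; stn[c(i, j)] <- stn[c(j, i)]
        out[[length(out) + 1L]] <- gene_order(nm, stn, nm[1])
      }
    } else if (kind == "transposition") {
      for (i in seq_len(n)) for (len in seq_len(n - 2L)) {
        blk <- wrap(seq(i, i + len - 1L))
        rest <- setdiff(seq_len(n), blk)
        for (k in seq_along(rest)) {
          nm <- c(ref$name[rest[seq_len(k)]], ref$name[blk],
                  ref$name[rest[-seq_len(k)]])
          stn <- c(ref$strand[rest[seq_len(k)]], ref$strand[blk],
                   ref$strand[rest[-seq_len(k)]])
          out[[length(out) + 1L]] <- gene_order(nm, stn, nm[1])
        }
      }
    } else {
      for (i in seq_len(n)) for (len in 2:(n - 1L)) {
        blk <- wrap(seq(i, i + len - 1L))
        nm <- ref$name; stn <- ref$strand
        nm[blk] <- rev(ref$name[blk])
        stn[blk] <- rev(ifelse(ref$strand[blk] == "J", "N", "J"))
        out[[length(out) + 1L]] <- gene_order(nm, stn, nm[1])
      }
    }
    out
  }
  hit <- function(kind) any(vapply(candidates(kind),
                                   function(cand) orders_equal(cand, obs),
                                   logical(1)))
  if (orders_equal(obs, ref)) return("identical")
  if (hit("swap")) return("adjacent_swap")
  if (hit("transposition")) return("block_transposition")
  if (hit("inversion")) return("inversion")
  "complex"
}

# TDRL minimum-copy oracle: a single k-copy TDRL of a contiguous block
# rewrites the block as a concatenation of k subsequences each in
# ancestral order, so the minimal k for a block equals 1 + the number
# of descents of the derived block read in ancestral indices; the
# global minimum scans all contiguous blocks whose outside is fixed
oracle_tdrl_min_copies <- function(anc, der) {
  if (identical(anc, der)) return(0L)
  n <- length(anc)
  best <- Inf
  for (i in seq_len(n)) for (j in i:n) {
    if (!identical(anc[-(i:j)], der[-(i:j)])) next
    if (!setequal(anc[i:j], der[i:j])) next
    idx <- match(der[i:j], anc[i:j])
    k <- 1L + sum(diff(idx) < 0L)
    if (k >= 2L) best <- min(best, k)
  }
  if (!is.finite(best)) NA_integer_ else as.integer(best)
}

# independent Smith-Waterman best-score oracle via Biostrings
oracle_sw_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 2, gapExtension = 2)
  Biostrings::score(pa)
}

# NG86 per-codon site/difference oracle by direct enumeration of the 9
# single-nucleotide mutations and the difference-position permutations
oracle_codon_sites <- function(codon) {
  code <- Biostrings::getGeneticCode("5")
  cs <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    ns <- 0L; nn <- 0L
    for (b in setdiff(c("A", "C", "G", "T"), cs[pos])) {
      alt <- cs; alt[pos] <- b
      aa2 <- code[[paste(alt, collapse = "")]]
      if (aa2 == "*") next
      if (aa2 == code[[codon]]) ns <- ns + 1L else nn <- nn + 1L
    }
    if (ns + nn > 0L) syn <- syn + ns / (ns + nn)
  }
  c(syn = syn, nonsyn = 3 - syn)
}
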