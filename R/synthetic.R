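# Synthetic annotated mitogenome generator with a full truth log, so
# that every analysis stage can be exercised against known ground
# truth: planted junction layout, planted same-strand transposition
# with a tandem-repeat-unit spacer carrying degenerate tRNA remnants,
# and planted nonsynonymous divergence.

# typical invertebrate mitochondrial PCG lengths (bp, incl. stop codon)
.PCG_LENGTHS <- c(ND2 = 1023, COX1 = 1536, COX2 = 687, ATP8 = 159,
                  ATP6 = 675, COX3 = 789, ND3 = 354, ND5 = 1716,
                  ND4 = 1344, ND4L = 291, ND6 = 510, CYTB = 1140,
                  ND1 = 939)

# default junction layout: 12 overlaps of 1-8 bp (always eating into a
# downstream tRNA, whose sequence is unconstrained) and 4 small
# intergenic spacers; every other junction abuts.  Keys are the
# junction's left gene.
.DEFAULT_OVERLAPS <- c(trnI = 1L, trnQ = 2L, COX1 = 8L, COX2 = 3L,
                       ND3 = 1L, trnA = 2L, trnR = 4L, trnN = 5L,
                       ND5 = 7L, ND4L = 1L, CYTB = 6L, ND1 = 2L)
.DEFAULT_SPACERS <- c(trnK = 9L, trnG = 17L, trnP = 5L, trnS2 = 12L)

#' Generator specification for synthetic mitogenomes
#'
#' The defaults emulate the structure of an AT-biased ~16.5 kb firefly
#' mitogenome: 37 genes plus control region in the ancestral insect
#' arrangement, base probabilities (A .471, T .334, G .074, C .121),
#' tRNAs of 60-75 bp, canonical PCG/rRNA lengths, 12 planted gene
#' overlaps (1-8 bp) and 4 small spacers; the control region is sized
#' to hit the genome length target exactly.  The default target of
#' 15,836 bp is chosen so that planting the default 710 bp
#' tandem-repeat spacer (see [plant_rearrangement()]) yields a derived
#' genome of 16,546 bp.
#'
#' @param seed Integer seed driving all randomness of the generator.
#' @param genome_length_target Total genome size in bp.
#' @param base_probs Named probabilities for A, T, G, C (sum to 1).
#' @param trna_len_range Uniform range for tRNA gene lengths.
#' @param pcg_lengths,rrn_lengths Named length vectors (bp).
#' @param overlaps,spacers Named integer vectors keyed by the left gene
#'   of the junction.
#' @param id Record identifier.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 1L,
                           genome_length_target = 15836L,
                           base_probs = c(A = 0.471, T = 0.334,
                                          G = 0.074, C = 0.121),
                           trna_len_range = c(60L, 75L),
                           pcg_lengths = .PCG_LENGTHS,
                           rrn_lengths = c(rrnL = 1285L, rrnS = 785L),
                           overlaps = .DEFAULT_OVERLAPS,
                           spacers = .DEFAULT_SPACERS,
                           id = "SYNMT01") {
  stopifnot(abs(sum(base_probs) - 1) < 1e-6,
            all(pcg_lengths %% 3L == 0L),
            all(overlaps >= 1L), all(spacers >= 1L))
  structure(list(seed = as.integer(seed),
                 genome_length_target = as.integer(genome_length_target),
                 base_probs = base_probs,
                 trna_len_range = trna_len_range,
                 pcg_lengths = pcg_lengths,
                 rrn_lengths = rrn_lengths,
                 overlaps = overlaps, spacers = spacers,
                 id = id),
            class = "generator_spec")
}

# a random in-frame CDS: ATG + non-stop codons + TAA (table 5 stops)
.random_cds <- function(len, probs) {
  ncod <- len %/% 3L
  stopifnot(ncod >= 2L)
  mids <- character(ncod - 2L)
  i <- 1L
  while (i <= length(mids)) {
    cod <- random_dna(3L, probs)
    if (cod %in% c("TAA", "TAG")) next
    mids[i] <- cod
    i <- i + 1L
  }
  paste0("ATG", paste(mids, collapse = ""), "TAA")
}

#' Generate a synthetic annotated mitogenome
#'
#' Lays the 37 genes + control region out in the ancestral insect
#' arrangement with the spec's junction plan, drawing every sequence
#' from the spec's base probabilities (PCGs as valid start..stop open
#' reading frames under the invertebrate mitochondrial code; N-strand
#' genes stored reverse-complemented).  Deterministic given the seed.
#'
#' @param spec A [generator_spec()].
#' @return A list with `record` (a [mitogenome_record()]) and `truth`,
#'   a log of every gene coordinate and junction gap as planted.
#' @export
generate_mitogenome <- function(spec = generator_spec()) {
  set.seed(spec$seed)
  ord <- ancestral_insect_order()
  genes <- ord$name
  strands <- setNames(ord$strand, genes)
  lens <- integer(length(genes)); names(lens) <- genes
  for (g in genes) {
    cls <- gene_class_of(g)
    lens[g] <- switch(cls,
      PCG = spec$pcg_lengths[[g]],
      tRNA = sample(spec$trna_len_range[1]:spec$trna_len_range[2], 1L),
      rRNA = spec$rrn_lengths[[g]],
      control_region = 0L)  # filled below
  }
  gaps <- setNames(rep(0L, length(genes)), genes)  # gap after each gene
  gaps[names(spec$overlaps)] <- -spec$overlaps
  gaps[names(spec$spacers)] <- spec$spacers
  cr_len <- spec$genome_length_target -
    (sum(lens[genes != "control_region"]) + sum(gaps))
  if (cr_len < 200L)
    stop("infeasible spec: genes exceed the genome length target ",
         "(control region would be ", cr_len, " bp)")
  lens["control_region"] <- cr_len

  # draw gene-strand sequences; base_probs describe the J (genome)
  # strand, so N-strand genes are drawn from complemented
  # probabilities to preserve the genome-wide strand skew
  comp_probs <- c(A = spec$base_probs[["T"]], T = spec$base_probs[["A"]],
                  G = spec$base_probs[["C"]], C = spec$base_probs[["G"]])
  gene_seq <- setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    pr <- if (strands[g] == "N") comp_probs else spec$base_probs
    gene_seq[[g]] <- if (gene_class_of(g) == "PCG")
      .random_cds(lens[g], pr)
    else random_dna(lens[g], pr)
  }

  built <- .assemble_genome(genes, strands, gene_seq, gaps, spec$base_probs)
  f <- gene_features(genes, gene_class_of(genes), strands[genes],
                     built$start[genes], built$end[genes])
  record <- mitogenome_record(spec$id, built$seq, f)
  truth <- list(spec = spec,
                coords = data.frame(name = genes,
                                    strand = unname(strands[genes]),
                                    start = unname(built$start[genes]),
                                    end = unname(built$end[genes]),
                                    length = unname(lens[genes])),
                gaps = data.frame(left = genes,
                                  right = c(genes[-1], genes[1]),
                                  gap = unname(gaps)),
                gap_seqs = built$gap_seqs,
                n_overlaps = sum(gaps < 0L),
                n_spacers = sum(gaps > 0L))
  list(record = record, truth = truth)
}

# concatenate gene pieces honoring gaps (random fill) and overlaps
# (downstream gene's genome-strand prefix is forced to the bases
# already laid down)
.assemble_genome <- function(genes, strands, gene_seq, gaps, probs) {
  pieces <- character(); gap_seqs <- list()
  start <- integer(length(genes)); names(start) <- genes
  end <- integer(length(genes)); names(end) <- genes
  pos <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    gseq <- gene_seq[[g]]
    genome_strand <- if (strands[g] == "N") revcomp(gseq) else gseq
    glen <- nchar(genome_strand)
    if (i > 1L) {
      gp <- gaps[[genes[i - 1L]]]
      if (gp > 0L) {
        fill <- random_dna(gp, probs)
        gap_seqs[[genes[i - 1L]]] <- fill
        pieces <- c(pieces, fill)
        pos <- pos + gp
      } else if (gp < 0L) {
        # overlap: drop the forced prefix (it already exists upstream)
        genome_strand <- substr(genome_strand, -gp + 1L, glen)
        start[g] <- pos + gp + 1L
        end[g] <- pos + gp + glen
        pieces <- c(pieces, genome_strand)
        pos <- end[g]
        next
      }
    }
    start[g] <- pos + 1L
    end[g] <- pos + glen
    pieces <- c(pieces, genome_strand)
    pos <- end[g]
  }
  # trailing gap after the last gene (wraps to the first); default 0
  gp <- gaps[[genes[length(genes)]]]
  if (gp > 0L) {
    fill <- random_dna(gp, probs)
    gap_seqs[[genes[length(genes)]]] <- fill
    pieces <- c(pieces, fill)
  }
  list(seq = paste(pieces, collapse = ""), start = start, end = end,
       gap_seqs = gap_seqs)
}

#' Plant a same-strand transposition with a tandem-repeat spacer
#'
#' Swaps two adjacent genes (each keeping its own strand) and inserts,
#' between the rearranged pair, an intergenic spacer of `n_tru` tandem
#' repeat units plus a trailing partial unit.  Each unit is a
#' degenerate copy of the displaced gene (its first `remnant_len`
#' bases, J-strand) followed by one identical random linker of
#' `linker_len` bp, mirroring the remnant + linker structure expected
#' under tandem duplication-random loss.  Optional point mutations are
#' planted at `mutation_rate` (Poisson over the spacer), and
#' `remnant_mutation_copies` places one A-to-G substitution inside the
#' remnant part of each named copy.
#'
#' @param record A [mitogenome_record()] (typically from
#'   [generate_mitogenome()]).
#' @param block Two adjacent gene names, upstream first (default
#'   `c("trnW", "trnC")`).
#' @param n_tru Number of full tandem repeat units.
#' @param remnant_len,linker_len,partial_len Unit structure in bp; the
#'   unit period is `remnant_len + linker_len` and must equal `period`
#'   when that is supplied.
#' @param period Optional explicit period (consistency check only).
#' @param mutation_rate Expected point mutations per spacer bp.
#' @param remnant_mutation_copies Integer vector of unit indices that
#'   receive one A-to-G remnant mutation each.
#' @param base_probs Base probabilities for the random linker (default
#'   AT-biased, matching the generator's genome-wide composition).
#' @param seed Integer seed for the spacer randomness.
#' @return A list with `record` (the derived genome) and `truth`
#'   (spacer string, unit, remnant offsets, planted mutations).
#' @export
plant_rearrangement <- function(record, block = c("trnW", "trnC"),
                                n_tru = 6L, remnant_len = 29L,
                                linker_len = 82L, partial_len = 44L,
                                period = NULL, mutation_rate = 0,
                                remnant_mutation_copies = integer(),
                                base_probs = c(A = 0.471, T = 0.334,
                                               G = 0.074, C = 0.121),
                                seed = 1L) {
  set.seed(seed)
  p <- remnant_len + linker_len
  if (!is.null(period) && period != p)
    stop("remnant_len + linker_len = ", p, " does not equal period ", period)
  if (partial_len > p) stop("partial unit longer than the period")
  f <- record$features[order(record$features$start), ]
  i1 <- match(block[1], f$name); i2 <- match(block[2], f$name)
  if (is.na(i1) || is.na(i2) || i2 != i1 + 1L)
    stop("block genes must be adjacent in the record")

  # displaced gene = the one ending up downstream after the swap
  down_gene <- block[1]
  down_seq_genome <- substr(record$sequence, f$start[i1], f$end[i1])
  remnant <- substr(down_seq_genome, 1L, remnant_len)
  if (nchar(remnant) < remnant_len)
    stop("remnant_len exceeds the displaced gene length")
  # the linker must leave the planted truth unambiguous: scanning the
  # assembled unit against the record's intact tRNAs has to recover
  # exactly the one planted remnant (full length, no extension into
  # the linker, no incidental second hit); otherwise redraw
  lib <- trna_library(record)
  unit <- NULL
  for (attempt in 1:200) {
    linker <- random_dna(linker_len, base_probs)
    cand <- paste0(remnant, linker)
    h <- scan_remnants(cand, lib)
    if (nrow(h) == 1L && h$spacer_offset == 1L &&
        h$length == remnant_len && h$mismatches == 0L &&
        h$strand == "J") { unit <- cand; break }
  }
  if (is.null(unit))
    stop("could not draw an unambiguous linker; ",
         "check remnant/linker parameters")
  spacer <- paste0(paste(rep(unit, n_tru), collapse = ""),
                   substr(unit, 1L, partial_len))
  mut_log <- data.frame(pos = integer(), from = character(),
                        to = character())
  sp <- chars(spacer)
  for (cp in remnant_mutation_copies) {
    # interior positions only, so the mutated copy still aligns as one
    # full-length remnant with a single internal mismatch
    inner <- 5L:max(5L, remnant_len - 4L)
    span <- (cp - 1L) * p + inner
    cand <- span[sp[span] == "A"]
    pos <- if (length(cand)) cand[sample.int(length(cand), 1L)]
           else span[sample.int(length(span), 1L)]
    to <- if (sp[pos] == "A") "G" else sample(setdiff(c("A", "C", "G", "T"), sp[pos]), 1L)
    mut_log <- rbind(mut_log, data.frame(pos = pos, from = sp[pos], to = to))
    sp[pos] <- to
  }
  if (mutation_rate > 0) {
    nm <- rpois(1L, mutation_rate * length(sp))
    if (nm > 0L) {
      posv <- sample.int(length(sp), min(nm, length(sp)))
      for (pos in posv) {
        to <- sample(setdiff(c("A", "C", "G", "T"), sp[pos]), 1L)
        mut_log <- rbind(mut_log,
                         data.frame(pos = pos, from = sp[pos], to = to))
        sp[pos] <- to
      }
    }
  }
  spacer <- paste(sp, collapse = "")

  # rebuild the genome with the block swapped and the spacer inserted
  jr <- junction_report(record)$junctions
  old_gap <- setNames(jr$gap, paste(jr$left, jr$right))
  order_new <- f$name
  order_new[c(i1, i2)] <- order_new[c(i2, i1)]
  piece_of <- function(name) {
    k <- match(name, f$name)
    substr(record$sequence, f$start[k], f$end[k])
  }
  gap_seq_of <- function(left, right, gap) {
    k <- match(left, f$name)
    substr(record$sequence, f$end[k] + 1L, f$end[k] + gap)
  }
  pieces <- character(); pos <- 0L
  start <- integer(length(order_new)); end <- integer(length(order_new))
  for (k in seq_along(order_new)) {
    g <- order_new[k]
    seq_g <- piece_of(g)
    if (k > 1L) {
      prev <- order_new[k - 1L]
      if (prev == block[2] && g == block[1]) {        # the new junction
        pieces <- c(pieces, spacer); pos <- pos + nchar(spacer)
      } else {
        gp <- old_gap[paste(prev, g)]
        if (is.na(gp)) gp <- 0L                       # new flank junction
        if (gp > 0L) {
          pieces <- c(pieces, gap_seq_of(prev, g, gp))
          pos <- pos + gp
        } else if (gp < 0L) {
          seq_g <- substr(seq_g, -gp + 1L, nchar(seq_g))
          start[k] <- pos + gp + 1L
          end[k] <- pos + gp + nchar(piece_of(g))
          pieces <- c(pieces, seq_g); pos <- end[k]
          next
        }
      }
    }
    start[k] <- pos + 1L
    end[k] <- pos + nchar(seq_g)
    pieces <- c(pieces, seq_g); pos <- end[k]
  }
  fi <- match(order_new, f$name)
  f2 <- gene_features(order_new, f$gene_class[fi], f$strand[fi],
                      start, end)
  rec2 <- mitogenome_record(record$id, paste(pieces, collapse = ""), f2)
  sp_start <- end[match(block[2], order_new)] + 1L
  truth <- list(block = block, n_tru = n_tru, period = p,
                remnant_len = remnant_len, linker_len = linker_len,
                partial_len = partial_len,
                unit = unit, spacer = spacer,
                spacer_length = nchar(spacer),
                spacer_start = sp_start,
                remnant_offsets = (seq_len(n_tru) - 1L) * p + 1L,
                mutations = mut_log)
  list(record = rec2, truth = truth)
}

#' Generate a nonsynonymously diverged copy of a genome
#'
#' For every protein-coding gene, each internal codon (start, stop and
#' the last two sense codons are left untouched so planted gene
#' overlaps stay intact) is hit with probability `nonsyn_rate` by one
#' random nonsynonymous single-nucleotide substitution that does not
#' create a stop codon.  Synonymous sites are never touched.
#'
#' @param record A [mitogenome_record()] with PCG annotations.
#' @param nonsyn_rate Per-codon substitution probability.
#' @param seed Integer seed.
#' @return A list with `record` (the diverged genome) and `truth`
#'   (per-gene and total substitution counts and positions).
#' @export
generate_diverged_pair <- function(record, nonsyn_rate, seed = 1L) {
  set.seed(seed)
  code <- invertebrate_mt_code()
  seq2 <- record$sequence
  f <- record$features
  total <- 0L
  per_gene <- list()
  for (idx in which(f$gene_class == "PCG")) {
    g <- f$name[idx]
    gseq <- extract_feature_seq(record, f[idx, ])
    cods <- substring(gseq, seq(1L, nchar(gseq), 3L),
                      seq(3L, nchar(gseq), 3L))
    ncod <- length(cods)
    hit_pos <- integer()
    for (ci in seq(2L, max(2L, ncod - 3L))) {
      if (runif(1L) >= nonsyn_rate) next
      alts <- .nonsyn_neighbors(cods[ci], code)
      if (!length(alts)) next
      cods[ci] <- alts[sample.int(length(alts), 1L)]
      hit_pos <- c(hit_pos, ci)
    }
    if (length(hit_pos)) {
      new_gseq <- paste(cods, collapse = "")
      genome_piece <- if (f$strand[idx] == "N") revcomp(new_gseq) else new_gseq
      substr(seq2, f$start[idx], f$end[idx]) <- genome_piece
      total <- total + length(hit_pos)
    }
    per_gene[[g]] <- hit_pos
  }
  rec2 <- mitogenome_record(paste0(record$id, "_div"), seq2, f,
                            record$topology)
  list(record = rec2,
       truth = list(nonsyn_rate = nonsyn_rate,
                    n_substitutions = total,
                    per_gene = per_gene))
}

# single-nt nonsynonymous neighbors of a codon that are not stops
.nonsyn_neighbors <- function(codon, code) {
  aa <- code[[codon]]
  cs <- chars(codon)
  out <- character()
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), cs[pos])) {
    alt <- cs; alt[pos] <- b
    alt <- paste(alt, collapse = "")
    aa2 <- code[[alt]]
    if (aa2 != "*" && aa2 != aa) out <- c(out, alt)
  }
  out
}

#' The packaged study-condition genome pair
#'
#' Convenience wrapper generating the ancestral synthetic mitogenome
#' (15,836 bp) and planting the default trnW/trnC transposition with
#' its 6 x 111 bp + 44 bp tandem-repeat spacer carrying one A-to-G
#' mutation in the fifth unit's remnant, for a derived genome of
#' 16,546 bp.
#'
#' @param seed Integer seed.
#' @return A list with `ancestral`, `derived` (both
#'   `generate_mitogenome()`-style lists) and `truth` of the planted
#'   event.
#' @export
study_genome <- function(seed = 1L) {
  anc <- generate_mitogenome(generator_spec(seed = seed))
  der <- plant_rearrangement(anc$record,
                             remnant_mutation_copies = 5L,
                             seed = seed + 1000L)
  list(ancestral = anc, derived = der$record, truth = der$truth,
       ancestral_truth = anc$truth)
}

#' The record's intact tRNA sequences as a remnant-scan library
#'
#' @param record A [mitogenome_record()].
#' @return Named character vector of tRNA gene sequences in reading
#'   orientation.
#' @export
trna_library <- function(record) {
  f <- record$features[record$features$gene_class == "tRNA", ]
  setNames(vapply(seq_len(nrow(f)),
                  function(i) extract_feature_seq(record, f[i, ]), ""),
           f$name)
}
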