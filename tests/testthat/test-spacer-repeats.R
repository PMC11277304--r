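test_that("spacer extraction returns the exact gap sequence", {
  L <- 40L
  seqs <- paste(rep("ACGT", 10), collapse = "")
  rec <- mitogenome_record(
    "S", seqs,
    gene_features(c("trnA", "trnR"), "tRNA", "J", c(1L, 14L), c(10L, 20L)))
  sp <- extract_spacer(rec, "trnA", "trnR")
  expect_equal(sp$length, 3L)
  expect_equal(sp$seq, substr(seqs, 11, 13))
  # the wrap-around junction is a legitimate circular spacer
  spw <- extract_spacer(rec, "trnR", "trnA")
  expect_equal(spw$length, 20L)
  expect_equal(spw$seq, substr(seqs, 21, 40))

  rec0 <- mitogenome_record(
    "S", seqs,
    gene_features(c("trnA", "trnR"), "tRNA", "J", c(1L, 11L), c(10L, 20L)))
  expect_error(extract_spacer(rec0, "trnA", "trnR"), "no spacer")
  expect_error(extract_spacer(rec, "trnA", "trnW"), "not adjacent")

  sg <- get_study()
  sp2 <- extract_spacer(sg$derived, "trnC", "trnW")
  expect_equal(sp2$seq, sg$truth$spacer)
  expect_equal(sp2$length, sg$truth$spacer_length)
})

test_that("exact tandems decompose to their true period and copy number", {
  d <- decompose_tandem(paste(rep("ACGTA", 4), collapse = ""),
                        min_period = 5L)
  expect_equal(length(d), 1L)
  expect_equal(d[[1]]$period, 5L)
  expect_equal(d[[1]]$copy_number, 4L)
  expect_equal(d[[1]]$partial_unit_length, 0L)
  expect_equal(d[[1]]$consensus, "ACGTA")
  expect_equal(decompose_tandem("ACGTACG"), list())

  set.seed(41)
  for (p in c(10L, 37L, 111L, 200L)) for (k in c(2L, 3L, 6L)) {
    unit <- random_dna(p)
    d <- decompose_tandem(paste(rep(unit, k), collapse = ""))
    expect_gte(length(d), 1L)
    expect_equal(d[[1]]$period, p, info = paste(p, k))
    expect_equal(d[[1]]$copy_number, k, info = paste(p, k))
    expect_equal(d[[1]]$partial_unit_length, 0L, info = paste(p, k))
  }
})

test_that("the TRU spacer decomposes with its partial unit and mismatch", {
  set.seed(13)
  unit <- random_dna(111)
  spacer <- paste0(paste(rep(unit, 6), collapse = ""), substr(unit, 1, 44))
  # one point mutation inside copy 5
  pos <- 4 * 111 + 57
  sp_chars <- strsplit(spacer, "")[[1]]
  sp_chars[pos] <- setdiff(c("A", "C", "G", "T"), sp_chars[pos])[1]
  spacer <- paste(sp_chars, collapse = "")

  d <- decompose_tandem(spacer)[[1]]
  expect_equal(d$period, 111L)
  expect_equal(d$copy_number, 6L)
  expect_equal(d$partial_unit_length, 44L)
  mm <- vapply(d$copy_alignments, `[[`, 0L, "mismatches")
  expect_equal(mm, c(0L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(d$copy_alignments[[5]]$mismatch_positions, 57L)

  # reconstruction: consensus + recorded mismatches reproduce the
  # covered span exactly
  cons <- strsplit(d$consensus, "")[[1]]
  rebuilt <- character(0)
  for (ca in d$copy_alignments) {
    cp <- cons
    for (m in ca$mismatch_positions)
      cp[m] <- substr(spacer, ca$start + m - 1L, ca$start + m - 1L)
    rebuilt <- c(rebuilt, cp)
  }
  rebuilt <- c(rebuilt, cons[seq_len(d$partial_unit_length)])
  expect_equal(paste(rebuilt, collapse = ""),
               substr(spacer, d$start, d$end))
})

test_that("random sequence yields no tandem decomposition at the null", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    if (length(decompose_tandem(random_dna(300))) > 0L) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("remnant scan finds planted fragments and matches the SW oracle", {
  set.seed(17)
  gene <- random_dna(70)
  frag <- substr(gene, 1, 29)
  spacer <- paste0(random_dna(100), frag, random_dna(100))
  h <- scan_remnants(spacer, c(trnX = gene))
  expect_equal(nrow(h), 1L)
  expect_equal(h$length, 29L)
  expect_equal(h$identity, 1)
  expect_equal(h$spacer_offset, 101L)
  expect_equal(h$strand, "J")

  # one interior substitution
  fr2 <- strsplit(frag, "")[[1]]
  fr2[15] <- setdiff(c("A", "C", "G", "T"), fr2[15])[1]
  spacer2 <- paste0(random_dna(100), paste(fr2, collapse = ""),
                    random_dna(100))
  h2 <- scan_remnants(spacer2, c(trnX = gene))
  expect_equal(h2$mismatches, 1L)
  expect_equal(h2$identity, 28 / 29)

  # reverse-complement planted fragment is found on the N strand
  spacer3 <- paste0(random_dna(80), revcomp(frag), random_dna(80))
  h3 <- scan_remnants(spacer3, c(trnX = gene))
  expect_equal(h3$strand, "N")
  # the hit covers the planted 29 bp interval (it may extend by a few
  # chance matches into the random flanks)
  expect_lte(h3$spacer_offset, 81L)
  expect_gte(h3$spacer_offset + h3$length - 1L, 109L)
})

test_that("the alignment kernel equals an independent implementation", {
  set.seed(23)
  for (i in 1:25) {
    a <- random_dna(sample(15:70, 1))
    b <- random_dna(sample(30:200, 1))
    al <- mitorearr:::.sw_align_cpp(a, b, 1, -1, 2, 2)
    expect_equal(al$score, oracle_sw_score(a, b), info = paste("case", i))
    # reported alignment strings rescore to the reported score
    ca <- strsplit(al$a_aln, "")[[1]]; cb <- strsplit(al$b_aln, "")[[1]]
    gap <- ca == "-" | cb == "-"
    runs <- sum(gap & !c(FALSE, gap[-length(gap)]))
    resc <- sum(ifelse(!gap & ca == cb, 1, ifelse(gap, -2, -1))) - 2 * runs
    expect_equal(resc, al$score)
  }
})

test_that("random spacers yield no remnant hits at the null", {
  seeds_with_hits <- 0L
  for (s in 1:50) {
    set.seed(2000 + s)
    lib <- setNames(replicate(5, random_dna(70)), paste0("trn", LETTERS[1:5]))
    if (nrow(scan_remnants(random_dna(300), lib)) > 0L)
      seeds_with_hits <- seeds_with_hits + 1L
  }
  expect_lte(seeds_with_hits, 1L)
})

test_that("TRU annotation assigns remnants, linkers and identity", {
  sg <- get_study()
  sp <- extract_spacer(sg$derived, "trnC", "trnW")
  d <- decompose_tandem(sp$seq)[[1]]
  h <- scan_remnants(sp, trna_library(sg$derived))
  tru <- annotate_trus(d, h, sp$seq)
  expect_equal(tru$n_remnant_copies, 6L)
  expect_equal(unname(tru$remnant_span[["length"]]), 29L)
  expect_equal(tru$linker_length, 82L)
  expect_true(tru$linkers_identical)
  expect_equal(dim(tru$linker_identity), c(6L, 6L))
  # the mutated fifth unit is the only one below identity 1
  below <- which(tru$copies$remnant_identity < 1)
  expect_equal(below, 5L)

  # no hits: every copy is all linker
  empty <- h[0, ]
  tru0 <- annotate_trus(d, empty, sp$seq)
  expect_equal(tru0$n_remnant_copies, 0L)
  expect_equal(tru0$linker_length, d$period)

  # a hit spanning a copy boundary is flagged, not assigned
  fake <- data.frame(source_gene = "trnW", strand = "J",
                     spacer_offset = d$start + d$period - 10L,
                     length = 20L, identity = 1, mismatches = 0L,
                     score = 20)
  trub <- annotate_trus(d, fake, sp$seq)
  expect_equal(trub$boundary_hits, 1L)
  expect_equal(trub$n_remnant_copies, 0L)
})

test_that("planted repeat parameters are recovered across seeds", {
  configs <- expand.grid(n = c(2L, 5L, 8L), r = c(20L, 29L, 40L))
  ok_zero <- 0L; tot_zero <- 0L
  ok_mut <- 0L; tot_mut <- 0L
  for (ci in seq_len(nrow(configs))) {
    n <- configs$n[ci]; r <- configs$r[ci]
    p <- r + 82L
    for (s in 1:7) {
      set.seed(3000 + 100 * ci + s)
      gene <- random_dna(70)
      # the planted unit must be unambiguous (no chance extension of
      # the fragment into the linker), as the generator guarantees
      unit <- NULL
      for (try in 1:50) {
        cand <- paste0(substr(gene, 1, r), random_dna(p - r))
        hh <- scan_remnants(cand, setNames(list(gene), "trnX"))
        if (nrow(hh) == 1L && hh$length == r && hh$mismatches == 0L) {
          unit <- cand; break
        }
      }
      expect_false(is.null(unit))
      for (rate in c(0, 0.01)) {
        sp <- strsplit(paste(rep(unit, n), collapse = ""), "")[[1]]
        nm <- rpois(1, rate * length(sp))
        if (nm > 0) for (pos in sample(length(sp), nm)) {
          sp[pos] <- sample(setdiff(c("A", "C", "G", "T"), sp[pos]), 1)
        }
        spacer <- paste(sp, collapse = "")
        d <- decompose_tandem(spacer)
        h <- scan_remnants(spacer, setNames(list(gene), "trnX"))
        got <- length(d) >= 1L && d[[1]]$period == p &&
          d[[1]]$copy_number == n && nrow(h) >= n - 1L
        if (rate == 0) {
          got <- got && nrow(h) == n && all(h$length == r) &&
            all(h$identity == 1)
          tot_zero <- tot_zero + 1L; ok_zero <- ok_zero + got
        } else {
          tot_mut <- tot_mut + 1L; ok_mut <- ok_mut + got
        }
      }
    }
  }
  expect_equal(ok_zero, tot_zero)          # exact recovery at rate 0
  expect_gte(ok_mut / tot_mut, 0.95)       # >= 95% at 1% mutation rate
})
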