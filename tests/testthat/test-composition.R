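test_that("base composition and strand skews follow their definitions", {
  bc <- base_composition("AATT")
  expect_equal(bc$freqA, 0.5)
  expect_equal(bc$freqT, 0.5)
  expect_equal(bc$at_skew, 0)
  expect_error(base_composition(""), "empty")

  # frequencies matching the published firefly composition give the
  # published skews at two-decimal rounding
  seq <- paste(c(rep("A", 471), rep("T", 334), rep("G", 74),
                 rep("C", 121)), collapse = "")
  bc2 <- base_composition(seq)
  expect_equal(round(bc2$at_skew, 2), 0.17)
  expect_equal(round(bc2$gc_skew, 2), -0.24)
  expect_equal(round(at_skew(0.471, 0.334), 2), 0.17)
  expect_equal(round(gc_skew(0.074, 0.121), 2), -0.24)

  # skews flip sign under reverse complement
  set.seed(11)
  for (i in 1:10) {
    s <- random_dna(500, c(A = .4, T = .3, G = .1, C = .2))
    expect_equal(base_composition(revcomp(s))$at_skew,
                 -base_composition(s)$at_skew)
    expect_equal(base_composition(revcomp(s))$gc_skew,
                 -base_composition(s)$gc_skew)
  }
  gc0 <- base_composition("ATAT")
  expect_equal(gc0$gc_skew, 0)
  expect_true(gc0$undefined_skew)
})

test_that("NG86 single-codon site and difference counts match enumeration", {
  expect_equal(ng86_ka("ATGATG", "ATGATG")$Ka, 0)

  # AAA (Lys) vs AAC (Asn): hand enumeration under the invertebrate mt
  # code gives 1/3 synonymous site at position 3 only (TAA excluded as
  # a stop at position 1), so each codon has 8/3 nonsynonymous sites
  # and the single difference is nonsynonymous
  r <- ng86_ka("AAA", "AAC")
  expect_equal(r$nonsyn_sites, 8 / 3)
  expect_equal(r$nonsyn_diffs, 1)
  expect_equal(r$syn_diffs, 0)
  expect_equal(r$pN, 3 / 8)
  expect_equal(r$Ka, -0.75 * log(1 - 0.5))
  expect_equal(oracle_codon_sites("AAA"), c(syn = 1 / 3, nonsyn = 8 / 3))

  # CCT (Pro) vs CAA (Gln): both two-step pathways are valid, one of
  # them passes through the synonymous CCT->CCA change, so the
  # pathway average is 0.5 synonymous + 1.5 nonsynonymous differences
  r2 <- ng86_ka("CCT", "CAA")
  expect_equal(r2$syn_diffs, 0.5)
  expect_equal(r2$nonsyn_diffs, 1.5)

  # per-codon site counts always sum to 3 for sense codons
  code <- invertebrate_mt_code()
  for (cod in names(code)[code != "*"]) {
    s <- mitorearr:::.codon_sites(cod)
    expect_equal(unname(s[["syn"]] + s[["nonsyn"]]), 3)
    expect_equal(s, oracle_codon_sites(cod))
  }
})

test_that("NG86 is symmetric and guards its error cases", {
  set.seed(21)
  for (i in 1:10) {
    a <- mitorearr:::.random_cds(60, c(A = .3, T = .3, G = .2, C = .2))
    b <- mitorearr:::.random_cds(60, c(A = .3, T = .3, G = .2, C = .2))
    ra <- ng86_ka(a, b); rb <- ng86_ka(b, a)
    expect_equal(ra$nonsyn_sites, rb$nonsyn_sites)
    expect_equal(ra$nonsyn_diffs, rb$nonsyn_diffs)
    expect_equal(ra$Ka, rb$Ka)
  }
  expect_error(ng86_ka("ATGA", "ATGA"), "multiple of 3")
  expect_error(ng86_ka("ATG", "ATGATG"), "length")
  # gap and ambiguity codons are skipped
  r <- ng86_ka("ATG---NNNAAA", "ATGTTTAAAAAA")
  expect_equal(r$n_skipped, 2L)
  expect_equal(r$n_codons, 2L)
})

test_that("Ka against a reference recovers planted divergence at genome scale", {
  sg <- get_study()
  anc <- sg$ancestral$record
  self <- ka_against_reference(anc, anc)
  expect_equal(self$concatenated$Ka, 0)
  expect_equal(length(self$per_gene), 13L)

  div <- generate_diverged_pair(anc, nonsyn_rate = 0.44, seed = 5)
  res <- ka_against_reference(anc, div$record)
  # expectation from the truth log: every substitution is one
  # nonsynonymous difference over the genome's nonsynonymous sites
  exp_pn <- div$truth$n_substitutions / res$concatenated$nonsyn_sites
  exp_ka <- -0.75 * log(1 - 4 / 3 * exp_pn)
  expect_lt(abs(res$concatenated$Ka - exp_ka) / exp_ka, 0.10)

  # truth-log substitution count equals the coding-position Hamming
  # distance between the two genomes
  ham <- 0L
  for (g in CANONICAL_PCGS) {
    a <- strsplit(extract_feature_seq(anc, g), "")[[1]]
    b <- strsplit(extract_feature_seq(div$record, g), "")[[1]]
    ham <- ham + sum(a != b)
  }
  expect_equal(ham, div$truth$n_substitutions)

  # a record with one PCG removed yields 12 per-gene entries + a skip
  anc12 <- anc
  anc12$features <- anc12$features[anc12$features$name != "ND6", ]
  expect_warning(res12 <- ka_against_reference(anc12, anc), "ND6")
  expect_equal(length(res12$per_gene), 12L)
  expect_equal(res12$skipped_genes, "ND6")
})

test_that("Ka is monotone in the planted nonsynonymous rate", {
  sg <- get_study()
  anc <- sg$ancestral$record
  kas <- vapply(c(0.05, 0.2, 0.44), function(rate) {
    div <- generate_diverged_pair(anc, nonsyn_rate = rate, seed = 31)
    ka_against_reference(anc, div$record)$concatenated$Ka
  }, numeric(1))
  expect_true(all(diff(kas) > 0))
})
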