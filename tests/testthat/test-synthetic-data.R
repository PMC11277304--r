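test_that("the generator is deterministic and honors its layout", {
  g1 <- generate_mitogenome(generator_spec(seed = 2))
  g2 <- generate_mitogenome(generator_spec(seed = 2))
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$record$features, g2$record$features)

  rec <- g1$record
  expect_equal(genome_length(rec), 15836L)
  expect_equal(nrow(rec$features), 38L)
  expect_equal(sum(rec$features$strand == "N"), 14L)
  expect_true(orders_equal(extract_gene_order(rec),
                           ancestral_insect_order()))
  validate_record(rec)

  # truth-log coordinates match the annotation
  expect_equal(rec$features$start[match(g1$truth$coords$name,
                                        rec$features$name)],
               g1$truth$coords$start)

  # an infeasible target errors
  expect_error(generate_mitogenome(generator_spec(genome_length_target = 14000L)),
               "infeasible")
})

test_that("generated composition tracks the target probabilities", {
  g <- generate_mitogenome(generator_spec(seed = 3))
  bc <- base_composition(g$record$sequence)
  # coding constraints (forced starts/stops, stop-codon avoidance)
  # shift frequencies by up to ~1.5% from the i.i.d. target
  expect_lt(abs(bc$freqA - 0.471), 0.02)
  expect_lt(abs(bc$freqT - 0.334), 0.02)
  expect_lt(abs(bc$freqG - 0.074), 0.02)
  expect_lt(abs(bc$freqC - 0.121), 0.02)
  expect_gt(bc$at_skew, 0.1)
  expect_lt(bc$gc_skew, -0.15)

  # protein-coding genes are clean open reading frames
  for (g13 in CANONICAL_PCGS) {
    aa <- translate_mt(extract_feature_seq(g$record, g13))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("the planted rearrangement has the advertised spacer anatomy", {
  sg <- get_study()
  expect_equal(genome_length(sg$derived), 16546L)
  expect_equal(sg$truth$spacer_length, 710L)
  expect_equal(sg$truth$period, 111L)
  expect_equal(nchar(sg$truth$unit), 111L)
  expect_equal(sg$truth$remnant_offsets, (0:5) * 111L + 1L)
  expect_equal(nrow(sg$truth$mutations), 1L)
  expect_equal(sg$truth$mutations$from, "A")
  expect_equal(sg$truth$mutations$to, "G")
  # mutation sits in the remnant part of unit 5
  expect_true(sg$truth$mutations$pos %in% (4L * 111L + 1:29))

  # parameter errors
  expect_error(plant_rearrangement(sg$ancestral$record, period = 100L),
               "period")
  expect_error(plant_rearrangement(sg$ancestral$record,
                                   block = c("trnW", "trnY")),
               "adjacent")

  # a two-unit spacer with no mutations decomposes exactly
  pr <- plant_rearrangement(sg$ancestral$record, n_tru = 2L,
                            partial_len = 0L, seed = 9)
  sp <- extract_spacer(pr$record, "trnC", "trnW")
  expect_equal(sp$length, 222L)
  d <- decompose_tandem(sp$seq)[[1]]
  expect_equal(d$period, 111L)
  expect_equal(d$copy_number, 2L)
  h <- scan_remnants(sp, trna_library(pr$record))
  expect_equal(nrow(h), 2L)
  expect_true(all(h$identity == 1))
})

test_that("diverged pairs follow their truth log", {
  anc <- get_study()$ancestral$record
  d0 <- generate_diverged_pair(anc, nonsyn_rate = 0, seed = 3)
  expect_identical(d0$record$sequence, anc$sequence)
  expect_equal(ka_against_reference(anc, d0$record)$concatenated$Ka, 0)

  d1a <- generate_diverged_pair(anc, nonsyn_rate = 0.2, seed = 4)
  d1b <- generate_diverged_pair(anc, nonsyn_rate = 0.2, seed = 4)
  expect_identical(d1a$record$sequence, d1b$record$sequence)
  expect_gt(d1a$truth$n_substitutions, 0L)
  # substitutions never touch synonymous sites: every changed codon
  # translates to a different amino acid
  for (g in CANONICAL_PCGS) {
    a <- extract_feature_seq(anc, g)
    b <- extract_feature_seq(d1a$record, g)
    pa <- strsplit(translate_mt(a), "")[[1]]
    pb <- strsplit(translate_mt(b), "")[[1]]
    ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    changed <- which(ca != cb)
    if (length(changed)) expect_true(all(pa[changed] != pb[changed]))
  }
})

test_that("pipeline closure: the full analysis reproduces the truth log", {
  sg <- get_study()
  rep <- run_full_analysis(sg$derived)
  expect_equal(rep$genome_length, 16546L)
  expect_equal(rep$junctions$n_overlaps, 12L)
  expect_equal(rep$junctions$n_spacers, 5L)
  expect_equal(rep$junctions$longest_spacer$length, 710L)
  expect_equal(rep$junctions$longest_spacer$left, "trnC")
  expect_equal(rep$junctions$longest_spacer$right, "trnW")
  expect_equal(rep$rearrangement$status, "adjacent_swap")
  expect_equal(rep$tandem$period, sg$truth$period)
  expect_equal(rep$tandem$copy_number, sg$truth$n_tru)
  expect_equal(rep$tandem$partial_unit_length, sg$truth$partial_len)
  expect_equal(rep$tru$n_remnant_copies, sg$truth$n_tru)
  expect_equal(unname(rep$tru$remnant_span[["length"]]),
               sg$truth$remnant_len)
  expect_equal(rep$tdrl[[1]]$copy_count, 8L)
})
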