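test_that("canonical gene name mapping covers the common synonym forms", {
  expect_equal(as.character(canonical_gene_name("tRNA-Trp")), "trnW")
  expect_equal(as.character(canonical_gene_name("trnW-UCA")), "trnW")
  expect_equal(as.character(canonical_gene_name("TW")), "trnW")
  expect_equal(as.character(canonical_gene_name("ND2")), "ND2")
  expect_equal(as.character(canonical_gene_name("COI")), "COX1")
  expect_equal(as.character(canonical_gene_name("cox1")), "COX1")
  expect_equal(as.character(canonical_gene_name("l-rRNA")), "rrnL")
  expect_equal(as.character(canonical_gene_name("16S ribosomal RNA")), "rrnL")
  expect_equal(as.character(canonical_gene_name("D-loop")), "control_region")
  expect_equal(as.character(canonical_gene_name("tRNA-Leu(uag)")), "trnL1")
  expect_equal(as.character(canonical_gene_name("trnS-tga")), "trnS2")
  out <- canonical_gene_name("hypothetical_orf")
  expect_equal(as.character(out), "hypothetical_orf")
  expect_true(attr(out, "non_canonical"))
  expect_false(attr(canonical_gene_name("trnW"), "non_canonical"))
})

test_that("feature extraction is strand- and origin-aware", {
  rec <- mitogenome_record(
    "X", "ATGCAA",
    gene_features("trnA", "tRNA", "J", 1L, 4L))
  expect_equal(extract_feature_seq(rec, "trnA"), "ATGC")
  rec_n <- mitogenome_record(
    "X", "ATGCAA", gene_features("trnA", "tRNA", "N", 1L, 4L))
  expect_equal(extract_feature_seq(rec_n, "trnA"), "GCAT")
  rec_w <- mitogenome_record(
    "X", "ATGCAA",
    gene_features("trnA", "tRNA", "J", 5L, 2L, wraps_origin = TRUE))
  expect_equal(extract_feature_seq(rec_w, "trnA"), "AAAT")
  # span length matches the extracted sequence on every strand/wrap
  for (r in list(rec, rec_n, rec_w)) {
    f <- r$features[1, ]
    expect_equal(nchar(extract_feature_seq(r, f)),
                 mitorearr:::span_length(f$start, f$end, f$wraps_origin,
                                         genome_length(r)))
  }
})

test_that("feature table + FASTA round-trips and rejects bad coordinates", {
  rec <- toy_record()
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fa")
  write_feature_table(rec, tsv)
  write_fasta(rec, fa)
  back <- parse_feature_table(tsv, fa)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$features, rec$features)

  bad <- data.frame(name = "trnW", class = "tRNA", strand = "J",
                    start = 5, end = 99)
  expect_error(parse_feature_table(bad, fa), "outside")
  rev <- data.frame(name = "trnW", class = "tRNA", strand = "J",
                    start = 9, end = 5)
  expect_error(parse_feature_table(rev, fa), "wraps_origin")
  empty <- data.frame(name = character(), class = character(),
                      strand = character(), start = integer(),
                      end = integer())
  rec0 <- parse_feature_table(empty, fa)
  expect_equal(nrow(rec0$features), 0L)
  dup <- data.frame(name = c("trnW", "tRNA-Trp"), class = "tRNA",
                    strand = "J", start = c(1, 10), end = c(5, 15))
  expect_warning(parse_feature_table(dup, fa), "duplicate")
})

test_that("GenBank text maps complement and origin-spanning locations", {
  gb <- c(
    "LOCUS       TESTREC 100 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     tRNA            complement(10..80)",
    '                     /product="tRNA-Trp"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//")
  rec <- parse_genbank(gb)
  f <- rec$features
  expect_equal(nrow(f), 1L)
  expect_equal(f$name, "trnW")
  expect_equal(f$gene_class, "tRNA")
  expect_equal(f$strand, "N")
  expect_equal(c(f$start, f$end), c(10L, 80L))
  expect_equal(rec$topology, "circular")
  expect_equal(genome_length(rec), 100L)

  gbw <- sub("complement\\(10\\.\\.80\\)", "join(95..100,1..7)", gb)
  gbw <- sub("tRNA   ", "CDS    ", gbw)
  recw <- parse_genbank(gbw)
  expect_true(recw$features$wraps_origin)
  expect_equal(nchar(extract_feature_seq(recw, recw$features[1, ])), 13L)

  expect_error(parse_genbank(gb[-grep("ORIGIN", gb)]), "ORIGIN")
  expect_warning(parse_genbank(sub("tRNA-Trp", "mystery-RNA", gb)),
                 "non-canonical")
})

test_that("GenBank serialization round-trips generator output", {
  sg <- get_study()
  for (rec in list(sg$ancestral$record, sg$derived)) {
    back <- parse_genbank(write_genbank(rec))
    expect_equal(back$sequence, rec$sequence)
    expect_equal(back$topology, rec$topology)
    rownames(back$features) <- rownames(rec$features) <- NULL
    expect_equal(back$features, rec$features)
  }
})

test_that("junction gaps follow the circular arithmetic", {
  mk <- function(s2, e2) mitogenome_record(
    "J", paste(rep("ACGT", 10), collapse = ""),
    gene_features(c("trnA", "trnR"), "tRNA", "J", c(1L, s2), c(10L, e2)))
  ov <- junction_report(mk(9L, 20L))
  expect_equal(ov$n_overlaps, 1L)
  expect_equal(ov$junctions$gap[1], -2L)
  sp <- junction_report(mk(14L, 20L))
  expect_equal(sp$n_spacers, 2L)  # the 3 bp gap plus the wrap junction
  expect_equal(sp$junctions$gap[1], 3L)
  # circular wrap junction from the last gene back to the first
  expect_equal(sp$junctions$gap[2], 1L - 20L - 1L + 40L)
})

test_that("junction report matches the generator's planted layout", {
  sg <- get_study()
  anc <- sg$ancestral
  jr <- junction_report(anc$record)
  expect_equal(jr$n_overlaps, anc$truth$n_overlaps)
  expect_equal(jr$n_spacers, anc$truth$n_spacers)
  expect_equal(jr$overlap_range, c(1L, 8L))
  planted <- anc$truth$gaps
  got <- jr$junctions
  expect_equal(got$gap[match(planted$left, got$left)], planted$gap)

  # genome-length closure: feature spans plus gaps tile the circle
  f <- anc$record$features
  expect_equal(sum(f$end - f$start + 1L) + sum(jr$junctions$gap),
               genome_length(anc$record))

  # reverse-complementing the record leaves the gap multiset unchanged
  jr_rc <- junction_report(revcomp_record(anc$record))
  expect_equal(sort(jr_rc$junctions$gap), sort(jr$junctions$gap))
})
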