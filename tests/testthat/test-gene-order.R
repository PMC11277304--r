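test_that("the ancestral insect arrangement has the canonical inventory", {
  anc <- ancestral_insect_order()
  expect_equal(length(anc$name), 38L)
  expect_setequal(anc$name, CANONICAL_GENES)
  i <- match("ND2", anc$name)
  expect_equal(anc$name[i + 0:3], c("ND2", "trnW", "trnC", "trnY"))
  expect_equal(anc$strand[i + 0:3], c("J", "J", "N", "N"))
  expect_equal(sum(anc$strand == "N"), 14L)
  expect_equal(compare_orders(anc, anc)$status, "identical")
})

test_that("gene orders are rotation invariant and round-trip as strings", {
  a <- gene_order(c("ND2", "trnW", "trnC", "trnY"),
                  c("J", "J", "N", "N"), origin_token = "ND2")
  b <- gene_order(c("trnC", "trnY", "ND2", "trnW"),
                  c("N", "N", "J", "J"), origin_token = "trnC")
  expect_true(orders_equal(a, b))
  expect_false(orders_equal(a, gene_order(c("ND2", "trnC", "trnW", "trnY"),
                                          c("J", "N", "J", "N"), "ND2")))
  expect_true(orders_equal(parse_gene_order(format_gene_order(a)), a))

  sg <- get_study()
  expect_true(orders_equal(extract_gene_order(sg$ancestral$record),
                           ancestral_insect_order()))
})

test_that("the trnC/trnW transposition classifies as an adjacent swap", {
  ref <- gene_order(c("ND2", "trnW", "trnC", "trnY"),
                    c("J", "J", "N", "N"), "ND2")
  obs <- gene_order(c("ND2", "trnC", "trnW", "trnY"),
                    c("J", "N", "J", "N"), "ND2")
  call <- compare_orders(obs, ref)
  expect_equal(call$status, "adjacent_swap")
  expect_setequal(call$affected_genes, c("trnW", "trnC"))
  expect_equal(call$window, c("ND2", "trnY"))
  expect_gt(call$breakpoint_count, 0L)

  # applying the called swap to the reference reproduces the observation
  i <- match(call$affected_genes[1], ref$name)
  nm <- ref$name; st <- ref$strand
  nm[i + 0:1] <- nm[i + 1:0]; st[i + 0:1] <- st[i + 1:0]
  expect_true(orders_equal(gene_order(nm, st, nm[1]), obs))

  expect_equal(compare_orders(ref, ref)$breakpoint_count, 0L)
})

test_that("whole-genome comparison flags the planted rearrangement", {
  sg <- get_study()
  call <- compare_orders(extract_gene_order(sg$derived),
                         ancestral_insect_order())
  expect_equal(call$status, "adjacent_swap")
  expect_setequal(call$affected_genes, c("trnW", "trnC"))
})

test_that("single-event classification agrees with the brute-force oracle", {
  set.seed(7)
  genes <- c("g1", "g2", "g3", "g4", "g5", "g6", "g7")
  for (trial in 1:30) {
    n <- sample(4:7, 1)
    strands <- sample(c("J", "N"), n, replace = TRUE)
    ref <- gene_order(genes[1:n], strands, "g1")
    kind <- sample(c("identical", "swap", "transposition", "inversion",
                     "shuffle"), 1)
    nm <- ref$name; st <- ref$strand
    if (kind == "swap") {
      i <- sample(n - 1L, 1)
      nm[i + 0:1] <- nm[i + 1:0]; st[i + 0:1] <- st[i + 1:0]
    } else if (kind == "transposition") {
      len <- sample(1:(n - 3L), 1)
      i <- sample(n - len, 1)
      blk <- i:(i + len - 1L)
      rest <- setdiff(1:n, blk)
      k <- sample(length(rest), 1)
      ord <- c(rest[seq_len(k)], blk, rest[-seq_len(k)])
      nm <- nm[ord]; st <- st[ord]
    } else if (kind == "inversion") {
      len <- sample(2:(n - 1L), 1)
      i <- sample(n - len + 1L, 1)
      blk <- i:(i + len - 1L)
      nm[blk] <- rev(nm[blk])
      st[blk] <- rev(ifelse(st[blk] == "J", "N", "J"))
    } else if (kind == "shuffle") {
      ord <- sample(n)
      nm <- nm[ord]; st <- st[ord]
    }
    obs <- gene_order(nm, st, nm[1])
    expect_equal(compare_orders(obs, ref)$status,
                 oracle_single_event(obs, ref),
                 info = paste("trial", trial, kind))
  }
})

test_that("comparison is invariant under simultaneous rotation", {
  ref <- ancestral_insect_order()
  obs <- extract_gene_order(get_study()$derived)
  for (anchor in c("COX1", "rrnS", "trnW")) {
    expect_equal(compare_orders(rotate_order(obs, anchor),
                                rotate_order(ref, anchor))$status,
                 "adjacent_swap")
  }
})
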