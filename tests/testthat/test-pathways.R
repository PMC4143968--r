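test_that("collection construction enforces the universe contract", {
  expect_error(gene_set_collection(character(0), list(A = "g1")), "empty universe")
  expect_error(gene_set_collection(letters, list(A = character(0))), "empty gene sets")
  expect_error(gene_set_collection(letters, list(A = "a", A = "b")), "duplicate")
  expect_error(gene_set_collection(letters[1:5], list(A = c("a", "z"))), "outside the universe")
})

test_that("per-set enrichment equals the brute-force hypergeometric tail", {
  # N = 100, K = 20, n = 10, k = 5 worked example
  universe <- sprintf("g%03d", 1:100)
  gsc <- gene_set_collection(universe, list(S = universe[1:20]))
  de <- c(universe[1:5], universe[96:100])  # 5 in the set, 5 out
  res <- enrich_sets(gsc, de)
  expect_equal(res$k, 5L)
  expect_equal(res$p_value, oracle_hyper_tail(5, 20, 10, 100), tolerance = 1e-14)
  # and against base R's Fisher test as a second, independent route
  ft <- stats::fisher.test(matrix(c(5, 15, 5, 75), 2, 2), alternative = "greater")
  expect_equal(res$p_value, ft$p.value, tolerance = 1e-12)
})

test_that("enrichment handles the degenerate contingency cases", {
  universe <- sprintf("g%02d", 1:50)
  gsc <- gene_set_collection(universe, list(A = universe[1:10], U = universe))
  res <- enrich_sets(gsc, universe[11:20])
  expect_equal(res$p_value[res$set_name == "A"], 1)   # k = 0
  expect_equal(res$p_value[res$set_name == "U"], 1)   # set = universe, certain event

  res0 <- enrich_sets(gsc, character(0))
  expect_true(all(res0$p_value == 1))

  expect_warning(out <- enrich_sets(gsc, c(universe[1], "not_a_gene")), "dropped")
  expect_equal(out$k[out$set_name == "A"], 1L)
})

test_that("hypergeometric tail agrees with brute-force summation on a parameter grid", {
  for (N in c(15, 30, 45)) {
    for (K in seq(2, N - 1, by = 7)) {
      for (n in seq(2, N - 1, by = 7)) {
        for (k in 0:min(K, n)) {
          expect_lt(abs(brainplex:::hyper_upper_tail(k, K, n, N) -
                          oracle_hyper_tail(k, K, n, N)), 1e-12)
        }
      }
    }
  }
})

test_that("BH q-values match a from-scratch step-up oracle", {
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("adding a DE gene to a set never increases its p-value", {
  universe <- sprintf("g%03d", 1:200)
  gsc <- gene_set_collection(universe, list(S = universe[1:40]))
  de_out <- universe[151:170]
  p_prev <- Inf
  for (extra in 0:5) {
    de <- c(de_out, universe[seq_len(extra)])
    # pad with non-set genes to hold n fixed
    de <- c(de, universe[101:(105 - extra)])
    p <- enrich_sets(gsc, de)$p_value
    expect_lte(p, p_prev + 1e-15)
    p_prev <- p
  }
})

test_that("intersection networks test only overlapping pairs and respect certain events", {
  universe <- sprintf("g%03d", 1:100)
  gsc <- gene_set_collection(universe, list(
    A = universe[1:30], B = universe[21:50], C = universe[60:80]
  ))
  pn <- intersection_network(gsc, universe[1:10], alpha = 0.05)
  expect_equal(nrow(pn$tests), 1L)  # only A-B intersect
  expect_setequal(c(pn$tests$set_a, pn$tests$set_b), c("A", "B"))

  # DE = universe makes every intersection a certain event: p = 1, no edges
  pn_all <- intersection_network(gsc, universe, alpha = 0.05)
  expect_true(all(pn_all$tests$p_value == 1))
  expect_equal(nrow(pn_all$edges), 0L)
})

test_that("a planted enriched intersection is recovered without false edges", {
  ov <- matrix(0, 4, 4)
  ov[1, 2] <- ov[2, 1] <- 0.3
  ov[2, 3] <- ov[3, 2] <- 0.3
  ov[3, 4] <- ov[4, 3] <- 0.3
  gu <- generate_gene_universe(
    800, c(P1 = 100, P2 = 100, P3 = 100, P4 = 100),
    overlap_fractions = ov, n_de = 80,
    enrichment_plan = list(list(sets = c("P1", "P2"), odds_ratio = 10)),
    seed = 31
  )
  pn <- intersection_network(as_gene_set_collection(gu), gu$de_genes, alpha = 0.05)
  expect_equal(nrow(pn$edges), 1L)
  expect_setequal(c(pn$edges$set_a, pn$edges$set_b), c("P1", "P2"))
  key <- paste(sort(c("P1", "P2"))[1], sort(c("P1", "P2"))[2], sep = "|")
  expect_equal(nrow(pn$interface[[key]]), 30L)
})

test_that("interface genes are the sorted intersection with DE flags", {
  universe <- c("g1", "g2", "g3", "g4", "g5")
  gsc <- gene_set_collection(universe, list(
    A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"), C = "g5",
    SUB = c("g2", "g3")
  ))
  ig <- interface_genes(gsc, "A", "B", de_genes = "g3")
  expect_equal(ig$gene, c("g2", "g3"))
  expect_equal(ig$de, c(FALSE, TRUE))
  expect_equal(nrow(interface_genes(gsc, "A", "C")), 0L)
  expect_equal(interface_genes(gsc, "SUB", "B")$gene, c("g2", "g3"))
  expect_error(interface_genes(gsc, "A", "nope"), "unknown set")
})

test_that("pathway networks export to GraphML with attributes intact", {
  universe <- sprintf("g%03d", 1:100)
  gsc <- gene_set_collection(universe, list(A = universe[1:30], B = universe[21:50]))
  pn <- intersection_network(gsc, universe[21:35], alpha = 0.5)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_pathway_graphml(pn, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), nrow(pn$edges))
})
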