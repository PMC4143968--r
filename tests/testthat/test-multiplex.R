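test_that("multiplex assembly validates layers and aligns label order", {
  set.seed(1)
  a <- random_layer(6, 0.4, "s1")
  b <- random_layer(6, 0.4, "s2")
  expect_error(build_multiplex(list(a)), "at least 2")
  expect_error(build_multiplex(list(a, b), layer_names = c("x", "x")), "duplicate")

  short <- layer_network(matrix(0L, 5, 5), feature_labels = default_labels(5))
  err <- tryCatch(build_multiplex(list(a, short)), error = conditionMessage)
  expect_match(err, "F006")  # symmetric difference is reported

  # shuffled label order is realigned, not treated as a different network
  perm <- sample(6)
  b_perm <- layer_network(b$adjacency[perm, perm],
                          feature_labels = b$feature_labels[perm],
                          state_label = "s2")
  mx1 <- build_multiplex(list(a, b))
  mx2 <- build_multiplex(list(a, b_perm))
  expect_identical(layer_overlap(mx1, "s1", "s2"), layer_overlap(mx2, "s1", "s2"))
  expect_identical(build_multiplex(list(a, b)), build_multiplex(list(a, b)))
})

test_that("overlap of the hand-enumerated 4-node example is exact", {
  adj_i <- matrix(0L, 4, 4); adj_j <- matrix(0L, 4, 4)
  adj_i[1, 2] <- adj_i[2, 1] <- 1L; adj_i[2, 3] <- adj_i[3, 2] <- 1L
  adj_j[2, 3] <- adj_j[3, 2] <- 1L; adj_j[3, 4] <- adj_j[4, 3] <- 1L
  labs <- letters[1:4]
  mx <- build_multiplex(list(layer_network(adj_i, feature_labels = labs),
                             layer_network(adj_j, feature_labels = labs)),
                        layer_names = c("i", "j"))
  ov <- layer_overlap(mx, "i", "j")
  expect_equal(ov$shared_ordered_pairs, 2L)
  expect_equal(ov$possible_ordered_pairs, 12L)
  expect_equal(ov$overlap_fraction, 2 / 12)
  expect_equal(ov$jaccard, 1 / 3)
})

test_that("overlap agrees with exhaustive ordered-pair enumeration on random multiplexes", {
  set.seed(2)
  for (i in 1:10) {
    a <- random_layer(15, runif(1, 0.1, 0.6), "a")
    b <- random_layer(15, runif(1, 0.1, 0.6), "b")
    mx <- build_multiplex(list(a, b))
    ov <- layer_overlap(mx, "a", "b")
    oracle <- oracle_layer_overlap(a$adjacency, b$adjacency)
    expect_identical(ov$shared_ordered_pairs, oracle$shared)
    expect_equal(ov$overlap_fraction, oracle$fraction)
    # bound: shared cells cannot exceed the smaller layer's link cells
    expect_lte(ov$shared_ordered_pairs,
               min(sum(a$adjacency), sum(b$adjacency)))
    expect_equal(ov$overlap_fraction, layer_overlap(mx, "b", "a")$overlap_fraction)
  }
  expect_error(layer_overlap(mx, "a", "nope"), "unknown layer")
})

test_that("identical and disjoint layers hit the overlap conventions", {
  set.seed(3)
  a <- random_layer(10, 0.3, "a")
  same <- layer_network(a$adjacency, feature_labels = a$feature_labels,
                        state_label = "b")
  mx <- build_multiplex(list(a, same))
  ov <- layer_overlap(mx, "a", "b")
  expect_equal(ov$overlap_fraction, sum(a$adjacency) / (10 * 9))  # density
  expect_equal(ov$jaccard, 1)

  compl <- layer_network(1L - a$adjacency - diag(1L, 10),
                         feature_labels = a$feature_labels, state_label = "c")
  mx2 <- build_multiplex(list(a, compl))
  ov2 <- layer_overlap(mx2, "a", "c")
  expect_equal(ov2$shared_ordered_pairs, 0L)
  expect_equal(ov2$jaccard, 0)
})

test_that("three 121-node layers give the expected ordered-pair denominator", {
  empty <- matrix(0L, 121, 121)
  labs <- default_labels(121)
  mk <- function(nm) layer_network(empty, feature_labels = labs, state_label = nm)
  mx <- build_multiplex(list(mk("a"), mk("b"), mk("c")))
  expect_equal(layer_overlap(mx, "a", "b")$possible_ordered_pairs, 14520L)
})

test_that("degree vectors follow the handshake lemma and preserve layer order", {
  set.seed(4)
  a <- random_layer(8, 0.4, "s1")
  b <- random_layer(8, 0.2, "s2")
  mx <- build_multiplex(list(a, b))
  dv <- degree_vectors(mx)
  expect_equal(dim(dv), c(8L, 2L))
  expect_equal(colnames(dv), c("s1", "s2"))
  expect_equal(sum(dv[, "s1"]), 2L * network_edge_count(a))
  expect_equal(sum(dv[, "s2"]), 2L * network_edge_count(b))

  iso <- layer_network(matrix(0L, 8, 8), feature_labels = a$feature_labels,
                       state_label = "s3")
  mx3 <- build_multiplex(list(iso, iso), layer_names = c("x", "y"))
  expect_true(all(degree_vectors(mx3) == 0L))
})

test_that("co-blocked nodes have more similar degree vectors across layers than cross-block nodes", {
  # unequal block sizes so a node's degree vector reflects its block
  tpl <- generate_state_template(21, 3, rho_within = 0.9)
  tpl$block_assignment <- rep(1:3, times = c(12, 6, 3))
  nets <- lapply(1:3, function(s) {
    ts <- simulate_feature_timeseries(tpl, 400, seed = 100 + s,
                                      state_label = paste0("rec", s))
    threshold_network(compute_similarity(ts), 0.8, state_label = paste0("rec", s))
  })
  dv <- degree_vectors(build_multiplex(nets))
  same <- outer(tpl$block_assignment, tpl$block_assignment, "==")
  d <- as.matrix(stats::dist(dv))
  ut <- upper.tri(d)
  expect_lt(mean(d[same & ut]), mean(d[!same & ut]))
})

test_that("layer similarity matrices are symmetric with the documented diagonal", {
  set.seed(5)
  a <- random_layer(12, 0.3, "a"); b <- random_layer(12, 0.5, "b")
  mx <- build_multiplex(list(a, b))
  mj <- layer_similarity_matrix(mx, "jaccard")
  expect_identical(mj, t(mj))
  expect_equal(unname(diag(mj)), c(1, 1))
  mo <- layer_similarity_matrix(mx, "overlap_fraction")
  expect_equal(mo["a", "a"], sum(a$adjacency) / (12 * 11))

  same <- layer_network(a$adjacency, feature_labels = a$feature_labels)
  mx_id <- build_multiplex(list(a, same), layer_names = c("x", "y"))
  expect_true(all(layer_similarity_matrix(mx_id, "jaccard") == 1))
})

test_that("match_state ranks deterministically with documented conventions", {
  set.seed(6)
  a <- random_layer(10, 0.3, "a"); b <- random_layer(10, 0.3, "b")
  mx <- build_multiplex(list(a, b))
  hit <- match_state(layer_network(a$adjacency, feature_labels = a$feature_labels),
                     mx, metric = "jaccard")
  expect_equal(hit$layer_name[1], "a")
  expect_equal(hit$similarity[1], 1)

  empty_q <- layer_network(matrix(0L, 10, 10), feature_labels = a$feature_labels)
  res <- match_state(empty_q, mx)
  expect_equal(res$similarity, c(0, 0))
  expect_equal(res$layer_name, c("a", "b"))  # lexicographic tie-break

  bad <- layer_network(matrix(0L, 10, 10), feature_labels = paste0("X", 1:10))
  expect_error(match_state(bad, mx), "symmetric difference")
})

test_that("a held-out recording maps to its own state template", {
  tpl_a <- generate_state_template(40, 4, rho_within = 0.9, layout = "contiguous")
  tpl_b <- generate_state_template(40, 4, rho_within = 0.9, layout = "interleaved")
  hits <- 0L
  for (s in 1:5) {
    lay <- function(tpl, seed, nm) {
      ts <- simulate_feature_timeseries(tpl, 300, seed = seed, state_label = nm)
      threshold_network(compute_similarity(ts), 0.8, state_label = nm)
    }
    mx <- build_multiplex(list(lay(tpl_a, 1000 + s, "stateA"),
                               lay(tpl_b, 2000 + s, "stateB")))
    query <- lay(tpl_a, 3000 + s, "query")
    if (match_state(query, mx)$layer_name[1] == "stateA") hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
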