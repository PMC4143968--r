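test_that("state templates partition features into near-equal contiguous blocks", {
  one <- generate_state_template(121, 1, rho_within = 0.5)
  expect_true(all(one$block_assignment == 1L))

  even <- generate_state_template(6, 3, rho_within = 0.5)
  expect_equal(unname(table(even$block_assignment)), rep(2L, 3), ignore_attr = TRUE)
  expect_equal(even$block_assignment, c(1L, 1L, 2L, 2L, 3L, 3L))

  uneven <- generate_state_template(121, 11, rho_within = 0.9)
  expect_equal(length(uneven$block_assignment), 121L)
  expect_true(all(table(uneven$block_assignment) == 11L))
  # contiguity: block ids are non-decreasing along the feature axis
  expect_true(all(diff(uneven$block_assignment) >= 0))

  expect_error(generate_state_template(5, 6, rho_within = 0.5), "n_blocks")
  expect_error(generate_state_template(10, 2, rho_within = 1.5), "rho_within")
})

test_that("contiguous and interleaved layouts with equal block counts share no co-blocked pair", {
  a <- generate_state_template(121, 11, rho_within = 0.9, layout = "contiguous")
  b <- generate_state_template(121, 11, rho_within = 0.9, layout = "interleaved")
  expect_equal(template_coblock_fraction(a, b), 0)
  expect_gt(template_coblock_fraction(a, a), 0)
})

test_that("simulation matches its generative model in the noise-free and null limits", {
  pure <- generate_state_template(12, 3, rho_within = 1, noise_sd = 0)
  ts <- simulate_feature_timeseries(pure, 50, seed = 7)
  r <- stats::cor(t(ts$values))
  same <- outer(pure$block_assignment, pure$block_assignment, "==")
  expect_true(all(abs(r[same] - 1) < 1e-12))

  # rho = 0: sample correlations stay inside the 99% Fisher-z null band
  null_tpl <- generate_state_template(30, 3, rho_within = 0)
  ts0 <- simulate_feature_timeseries(null_tpl, 500, seed = 11)
  r0 <- stats::cor(t(ts0$values))
  band <- stats::qnorm(0.995) / sqrt(500 - 3)
  off <- abs(atanh(r0[upper.tri(r0)]))
  expect_gte(mean(off <= band), 0.97)
})

test_that("within-block correlation converges to the closed-form factor-model value", {
  # population correlation rho / (rho + (1 - rho) * noise_sd^2)
  tpl <- generate_state_template(20, 4, rho_within = 0.6, noise_sd = 2)
  ts <- simulate_feature_timeseries(tpl, 5000, seed = 3)
  r <- stats::cor(t(ts$values))
  same <- outer(tpl$block_assignment, tpl$block_assignment, "==") & upper.tri(r)
  expected <- 0.6 / (0.6 + 0.4 * 4)
  expect_lt(abs(mean(r[same]) - expected), 0.02)
  # cross-block pairs are independent by construction
  diff_blk <- !outer(tpl$block_assignment, tpl$block_assignment, "==") & upper.tri(r)
  expect_lt(abs(mean(r[diff_blk])), 0.02)
})

test_that("generators are bit-identical for a fixed seed and leave the RNG alone", {
  tpl <- generate_state_template(15, 3, rho_within = 0.8)
  a <- simulate_feature_timeseries(tpl, 100, seed = 42)
  b <- simulate_feature_timeseries(tpl, 100, seed = 42)
  expect_identical(a$values, b$values)
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_feature_timeseries(tpl, 50, seed = 1))
  expect_identical(before, .Random.seed)

  expect_error(simulate_feature_timeseries(tpl, 2, seed = 1), "n_timepoints")
})

test_that("AR(1) smoothing preserves the planted correlation structure", {
  tpl <- generate_state_template(10, 2, rho_within = 0.9)
  ts <- simulate_feature_timeseries(tpl, 2000, seed = 5, ar = 0.6)
  r <- stats::cor(t(ts$values))
  same <- outer(tpl$block_assignment, tpl$block_assignment, "==") & upper.tri(r)
  expect_lt(abs(mean(r[same]) - 0.9), 0.05)
})

test_that("gene universes realise requested overlaps exactly and respect edge cases", {
  ov <- matrix(0, 3, 3)
  ov[1, 2] <- ov[2, 1] <- 0.3
  gu <- generate_gene_universe(500, c(A = 50, B = 50, C = 40),
                               overlap_fractions = ov, n_de = 30, seed = 2)
  expect_length(intersect(gu$sets$A, gu$sets$B), 15L)  # round(0.3 * 50)
  expect_length(intersect(gu$sets$A, gu$sets$C), 0L)
  expect_length(intersect(gu$sets$B, gu$sets$C), 0L)
  expect_true(all(gu$de_genes %in% gu$genes))
  expect_true(all(vapply(gu$sets, function(s) all(s %in% gu$genes), logical(1))))

  none <- generate_gene_universe(100, c(A = 10), n_de = 0, seed = 1)
  expect_identical(none$de_genes, character(0))

  expect_error(
    generate_gene_universe(60, c(A = 50, B = 50), overlap_fractions = 0,
                           n_de = 5, seed = 1),
    "infeasible"
  )
})

test_that("planted enrichment oversamples DE genes in the target intersection", {
  ov <- matrix(0, 2, 2); ov[1, 2] <- ov[2, 1] <- 0.5
  gu <- generate_gene_universe(
    1000, c(A = 60, B = 60), overlap_fractions = ov, n_de = 100,
    enrichment_plan = list(list(sets = c("A", "B"), odds_ratio = 10)),
    seed = 9
  )
  inter <- intersect(gu$sets$A, gu$sets$B)
  rate_in <- mean(inter %in% gu$de_genes)
  rate_out <- mean(setdiff(gu$genes, inter) %in% gu$de_genes)
  expect_gt(rate_in, 3 * rate_out)
})

test_that("with no enrichment plan, set p-values are null-calibrated", {
  # rejection rate at alpha stays below alpha + 3*SE (hypergeometric
  # p-values are discrete, hence super-uniform: one-sided bound)
  gu0 <- generate_gene_universe(400, c(A = 60, B = 80, C = 100), n_de = 0, seed = 1)
  gsc <- as_gene_set_collection(gu0)
  alpha <- 0.1
  n_rep <- 500
  rejected <- 0L
  total <- 0L
  set.seed(123)
  for (rep in seq_len(n_rep)) {
    de <- sample(gu0$genes, 40)
    res <- enrich_sets(gsc, de)
    rejected <- rejected + sum(res$p_value <= alpha)
    total <- total + nrow(res)
  }
  se <- sqrt(alpha * (1 - alpha) / total)
  expect_lte(rejected / total, alpha + 3 * se)
})
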