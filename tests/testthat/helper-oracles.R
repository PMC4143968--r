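# Independent oracles used across the suite. These deliberately use naive
# exhaustive computations so they stay independent of the package's own
# code paths.

# overlap of two layers by explicit enumeration of all N(N-1) ordered pairs
oracle_layer_overlap <- function(adj_a, adj_b) {
  n <- nrow(adj_a)
  shared <- 0L
  for (r in seq_len(n)) {
    for (cc in seq_len(n)) {
      if (r == cc) next
      if (adj_a[r, cc] == 1L && adj_b[r, cc] == 1L) shared <- shared + 1L
    }
  }
  list(shared = shared, possible = n * (n - 1L),
       fraction = shared / (n * (n - 1L)))
}

# hypergeometric upper tail P(X >= k) by brute-force summation
oracle_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# random symmetric binary layer with given link probability
random_layer <- function(n, p_link, state_label = "") {
  m <- matrix(0L, n, n)
  ut <- upper.tri(m)
  m[ut] <- stats::rbinom(sum(ut), 1L, p_link)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  layer_network(m, feature_labels = default_labels(n),
                state_label = state_label)
}

default_labels <- function(n) sprintf("F%03d", seq_len(n))

# wrap a plain symmetric matrix as a similarity object
make_sim <- function(m, labels = default_labels(nrow(m)), method = "pearson") {
  diag(m) <- 1
  similarity_matrix(m, method = method, feature_labels = labels)
}

# two-feature recording from explicit series
ts_from_rows <- function(...) {
  rows <- list(...)
  feature_timeseries(do.call(rbind, rows))
}
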