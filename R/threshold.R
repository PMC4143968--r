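#' Threshold a similarity matrix into a binary layer network
#'
#' A link is drawn between two features when their coefficient strictly
#' exceeds the threshold: `r > t` in `"signed"` mode (the default,
#' positive co-activation only) or `|r| > t` in `"absolute"` mode (which
#' also captures strong anti-correlation). The diagonal is always zero —
#' the layer is a simple undirected graph.
#'
#' @param sim A [similarity_matrix()].
#' @param r_threshold Cutoff; in `(-1, 1)` for signed mode, `(0, 1)` for
#'   absolute mode.
#' @param mode `"signed"` or `"absolute"`.
#' @param state_label Optional state label carried on the layer.
#' @return An object of class `layer_network`: `adjacency` (0/1 integer
#'   matrix), `threshold`, `mode`, `feature_labels`, `state_label`.
#' @export
#' @examples
#' m <- matrix(c(1, .85, .5, .85, 1, .2, .5, .2, 1), 3, 3)
#' net <- threshold_network(similarity_matrix(m, "pearson", c("a","b","c")), 0.8)
#' network_edge_count(net)  # 1
threshold_network <- function(sim, r_threshold, mode = c("signed", "absolute"),
                              state_label = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  mode <- match.arg(mode)
  r_threshold <- as.numeric(r_threshold)
  if (mode == "signed" && (r_threshold <= -1 || r_threshold >= 1)) {
    stop("signed `r_threshold` must lie in (-1, 1)")
  }
  if (mode == "absolute" && (r_threshold <= 0 || r_threshold >= 1)) {
    stop("absolute `r_threshold` must lie in (0, 1)")
  }
  v <- if (mode == "absolute") abs(sim$values) else sim$values
  adj <- (v > r_threshold) * 1L
  storage.mode(adj) <- "integer"
  diag(adj) <- 0L
  layer_network(adj, threshold = r_threshold, mode = mode,
                feature_labels = sim$feature_labels,
                state_label = if (is.null(state_label)) "" else state_label)
}

#' Layer network constructor
#'
#' Validates and wraps a binary adjacency matrix as one layer of a
#' multiplex: symmetric, zero-diagonal, 0/1 entries, labelled nodes.
#'
#' @param adjacency 0/1 square matrix.
#' @param threshold Coefficient cutoff that produced it (`NA` if external).
#' @param mode `"signed"` or `"absolute"`.
#' @param feature_labels Node labels.
#' @param state_label State label.
#' @return An object of class `layer_network`.
#' @export
layer_network <- function(adjacency, threshold = NA_real_,
                          mode = c("signed", "absolute"),
                          feature_labels = rownames(adjacency),
                          state_label = "") {
  mode <- match.arg(mode)
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("`adjacency` must be a square matrix")
  }
  if (!all(adjacency %in% c(0L, 1L))) stop("`adjacency` must be binary (0/1)")
  if (any(adjacency != t(adjacency))) stop("`adjacency` must be symmetric")
  if (any(diag(adjacency) != 0L)) stop("`adjacency` must have a zero diagonal (no self-loops)")
  if (is.null(feature_labels)) feature_labels <- default_feature_labels(nrow(adjacency))
  feature_labels <- as.character(feature_labels)
  if (anyDuplicated(feature_labels)) stop("feature labels must be unique")
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(feature_labels, feature_labels)
  structure(list(adjacency = adjacency, threshold = as.numeric(threshold),
                 mode = mode, feature_labels = feature_labels,
                 state_label = as.character(state_label)[1]),
            class = "layer_network")
}

#' @export
print.layer_network <- function(x, ...) {
  cat(sprintf("<layer_network> %d nodes, %d links, threshold %s (%s), state \"%s\"\n",
              nrow(x$adjacency), network_edge_count(x),
              format(x$threshold), x$mode, x$state_label))
  invisible(x)
}

#' Number of undirected links in a layer
#' @param net A [layer_network()].
#' @return Integer link count (each unordered pair once).
#' @export
network_edge_count <- function(net) {
  stopifnot(inherits(net, "layer_network"))
  sum(net$adjacency) %/% 2L
}

#' Edge list of a layer
#' @param net A [layer_network()].
#' @return Two-column character matrix of endpoints (`from < to`
#'   lexicographically by position), zero rows for an empty layer.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "layer_network"))
  idx <- which(net$adjacency == 1L & upper.tri(net$adjacency), arr.ind = TRUE)
  cbind(from = net$feature_labels[idx[, 1]],
        to = net$feature_labels[idx[, 2]])
}

# unordered link set as "i|j" keys with i < j (row/col positions)
edge_keys <- function(adjacency) {
  idx <- which(adjacency == 1L & upper.tri(adjacency))
  as.character(idx)
}

#' Jaccard similarity of two link sets
#'
#' `|intersection| / |union|` over unordered links; two empty link sets
#' have Jaccard 1 by convention (documented: an empty network is
#' "identical" to another empty network).
#'
#' @param a,b `layer_network` objects over node sets of equal size and
#'   identical ordering.
#' @return Jaccard index in `[0, 1]`.
#' @export
link_jaccard <- function(a, b) {
  stopifnot(inherits(a, "layer_network"), inherits(b, "layer_network"))
  if (nrow(a$adjacency) != nrow(b$adjacency)) stop("layers differ in node count")
  ea <- edge_keys(a$adjacency)
  eb <- edge_keys(b$adjacency)
  if (!length(ea) && !length(eb)) return(1)
  length(intersect(ea, eb)) / length(union(ea, eb))
}

#' Threshold robustness sweep
#'
#' Thresholds the same similarity matrix over a grid and reports, for each
#' cutoff, the layer, its link count, and the Jaccard similarity of its
#' link set to the previous (lower) cutoff's — high consecutive Jaccard
#' across a band of thresholds means the reconstructed network is not an
#' artifact of one arbitrary cutoff. Link sets shrink monotonically as the
#' threshold rises.
#'
#' @param sim A [similarity_matrix()].
#' @param r_min,r_max Sweep bounds, `r_min < r_max`.
#' @param step Positive grid step.
#' @param mode `"signed"` or `"absolute"`.
#' @return An object of class `threshold_sweep`: a list of records
#'   (`threshold`, `network`, `edge_count`, `jaccard_prev`) plus an
#'   `as.data.frame` method for the numeric summary. `jaccard_prev` is
#'   `NA` for the first grid point; between two empty link sets it is 1 by
#'   convention.
#' @export
threshold_sweep <- function(sim, r_min = 0.75, r_max = 0.85, step = 0.05,
                            mode = c("signed", "absolute")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  mode <- match.arg(mode)
  if (!(r_min < r_max)) stop("empty sweep range: need r_min < r_max")
  if (step <= 0) stop("`step` must be positive")
  thresholds <- seq(r_min, r_max, by = step)
  records <- vector("list", length(thresholds))
  prev <- NULL
  for (i in seq_along(thresholds)) {
    net <- threshold_network(sim, thresholds[i], mode = mode)
    jac <- if (is.null(prev)) NA_real_ else link_jaccard(prev, net)
    records[[i]] <- list(threshold = thresholds[i], network = net,
                         edge_count = network_edge_count(net),
                         jaccard_prev = jac)
    prev <- net
  }
  structure(records, class = "threshold_sweep")
}

#' @export
as.data.frame.threshold_sweep <- function(x, ...) {
  data.frame(
    threshold = vapply(x, `[[`, numeric(1), "threshold"),
    edge_count = vapply(x, function(r) as.numeric(r$edge_count), numeric(1)),
    jaccard_prev = vapply(x, `[[`, numeric(1), "jaccard_prev")
  )
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep>\n")
  print(as.data.frame(x))
  invisible(x)
}
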