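#' Assemble per-state layers into a multiplex network
#'
#' A multiplex is an ordered stack of layer networks over one shared,
#' identically ordered node set: row/column i means the same feature in
#' every layer, so inter-layer comparisons (overlap, degree vectors) are
#' meaningful cell by cell. Layers whose labels arrive in a different
#' order are realigned to the first layer's order; layers whose label
#' *sets* differ are rejected.
#'
#' @param networks List of [layer_network()] objects (>= 2).
#' @param layer_names Unique names for the layers; defaults to the layers'
#'   state labels.
#' @return An object of class `multiplex_network`: `layers` (named list of
#'   aligned `layer_network`s), `node_labels`, `layer_names`.
#' @export
#' @examples
#' m <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' l1 <- layer_network(m, state_label = "s1"); l2 <- layer_network(m, state_label = "s2")
#' mx <- build_multiplex(list(l1, l2))
build_multiplex <- function(networks, layer_names = NULL) {
  if (!is.list(networks) || length(networks) < 2L) {
    stop("a multiplex needs at least 2 layers")
  }
  if (!all(vapply(networks, inherits, logical(1), "layer_network"))) {
    stop("every element of `networks` must be a layer_network")
  }
  if (is.null(layer_names)) {
    layer_names <- vapply(networks, `[[`, character(1), "state_label")
    empty <- !nzchar(layer_names)
    layer_names[empty] <- paste0("layer", which(empty))
  }
  layer_names <- as.character(layer_names)
  if (length(layer_names) != length(networks)) {
    stop("`layer_names` must name every layer")
  }
  if (anyDuplicated(layer_names)) {
    stop("duplicate layer names: ",
         paste(unique(layer_names[duplicated(layer_names)]), collapse = ", "))
  }
  ref <- networks[[1]]$feature_labels
  aligned <- lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    labs <- net$feature_labels
    if (!setequal(labs, ref) || length(labs) != length(ref)) {
      sdiff <- c(setdiff(ref, labs), setdiff(labs, ref))
      stop("layer \"", layer_names[i], "\" has a different node set; ",
           "symmetric difference: ", paste(sdiff, collapse = ", "))
    }
    ord <- match(ref, labs)
    net$adjacency <- net$adjacency[ord, ord, drop = FALSE]
    net$feature_labels <- ref
    net
  })
  names(aligned) <- layer_names
  structure(list(layers = aligned, node_labels = ref,
                 layer_names = layer_names),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  counts <- vapply(x$layers, network_edge_count, integer(1))
  cat(sprintf("<multiplex_network> %d layers over %d nodes\n",
              length(x$layers), length(x$node_labels)))
  for (nm in x$layer_names) {
    cat(sprintf("  %-12s %d links\n", nm, counts[[nm]]))
  }
  invisible(x)
}

#' Link overlap between two multiplex layers
#'
#' Counts the off-diagonal adjacency cells equal to 1 in both layers and
#' reports the fraction of the `N(N-1)` possible ordered pairs that they
#' represent. The networks are undirected, so each shared link contributes
#' two ordered cells — but the denominator double-counts in exactly the
#' same way, so the fraction is identical to the unordered one. The
#' ordered-pair convention is kept because it is the standard way these
#' overlaps are quoted for adjacency-matrix "heatmap" comparisons. A
#' density-free Jaccard index over unordered link sets is reported
#' alongside (`jaccard(empty, empty) = 1` by convention).
#'
#' @param mx A [build_multiplex()] result.
#' @param i,j Layer names.
#' @return An object of class `overlap_result`: `layer_pair`,
#'   `shared_ordered_pairs`, `possible_ordered_pairs`, `overlap_fraction`,
#'   `jaccard`.
#' @export
layer_overlap <- function(mx, i, j) {
  stopifnot(inherits(mx, "multiplex_network"))
  for (nm in c(i, j)) {
    if (!nm %in% mx$layer_names) {
      stop("unknown layer name \"", nm, "\"; available: ",
           paste(mx$layer_names, collapse = ", "))
    }
  }
  a <- mx$layers[[i]]$adjacency
  b <- mx$layers[[j]]$adjacency
  n <- nrow(a)
  shared <- sum(a == 1L & b == 1L)  # diagonal is 0 in both by invariant
  possible <- n * (n - 1L)
  ea <- edge_keys(a)
  eb <- edge_keys(b)
  jac <- if (!length(ea) && !length(eb)) 1 else {
    length(intersect(ea, eb)) / length(union(ea, eb))
  }
  structure(list(layer_pair = c(i, j),
                 shared_ordered_pairs = as.integer(shared),
                 possible_ordered_pairs = as.integer(possible),
                 overlap_fraction = shared / possible,
                 jaccard = jac),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %s ~ %s: %d / %d ordered pairs shared (%.2f%%), jaccard %.3f\n",
              x$layer_pair[1], x$layer_pair[2], x$shared_ordered_pairs,
              x$possible_ordered_pairs, 100 * x$overlap_fraction, x$jaccard))
  invisible(x)
}

#' Per-node degree vectors across layers
#'
#' In a single network a node's connectivity is a scalar; in a multiplex
#' it becomes a vector with one entry per layer. Rows are nodes, columns
#' layers (layer order preserved).
#'
#' @param mx A [build_multiplex()] result.
#' @return Integer matrix, `n_nodes x n_layers`, dimnames set.
#' @export
degree_vectors <- function(mx) {
  stopifnot(inherits(mx, "multiplex_network"))
  out <- vapply(mx$layers, function(l) as.integer(rowSums(l$adjacency)),
                integer(length(mx$node_labels)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)  # single-node guard
  dimnames(out) <- list(mx$node_labels, mx$layer_names)
  out
}

#' Layer-by-layer similarity matrix
#'
#' Pairwise similarity of all layers under one metric, the basis for
#' classifying recordings into states. With `"overlap_fraction"` the
#' diagonal holds each layer's link density (its overlap with itself);
#' with `"jaccard"` the diagonal is 1.
#'
#' @param mx A [build_multiplex()] result.
#' @param metric `"overlap_fraction"` or `"jaccard"`.
#' @return Symmetric numeric matrix with layer names as dimnames.
#' @export
layer_similarity_matrix <- function(mx, metric = c("overlap_fraction", "jaccard")) {
  stopifnot(inherits(mx, "multiplex_network"))
  metric <- match.arg(metric)
  k <- length(mx$layer_names)
  out <- matrix(0, k, k, dimnames = list(mx$layer_names, mx$layer_names))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (b < a) next
      ov <- layer_overlap(mx, mx$layer_names[a], mx$layer_names[b])
      out[a, b] <- out[b, a] <- ov[[metric]]
    }
  }
  out
}

#' Rank library layers by similarity to a query recording
#'
#' Maps a new thresholded recording onto a library of known states: every
#' library layer is scored against the query under the chosen metric and
#' returned in descending order, ties broken lexicographically by layer
#' name so the ranking is deterministic. Query nodes must match the
#' library's node set (order may differ; it is realigned).
#'
#' @param query A [layer_network()].
#' @param library A [build_multiplex()] result.
#' @param metric `"jaccard"` (default, density-robust) or
#'   `"overlap_fraction"`.
#' @return Data frame with columns `layer_name`, `similarity`, best first.
#' @export
match_state <- function(query, library,
                        metric = c("jaccard", "overlap_fraction")) {
  stopifnot(inherits(query, "layer_network"),
            inherits(library, "multiplex_network"))
  metric <- match.arg(metric)
  if (!setequal(query$feature_labels, library$node_labels) ||
      length(query$feature_labels) != length(library$node_labels)) {
    sdiff <- c(setdiff(library$node_labels, query$feature_labels),
               setdiff(query$feature_labels, library$node_labels))
    stop("query node set does not match the library; symmetric difference: ",
         paste(sdiff, collapse = ", "))
  }
  ord <- match(library$node_labels, query$feature_labels)
  qadj <- query$adjacency[ord, ord, drop = FALSE]
  n <- nrow(qadj)
  eq <- edge_keys(qadj)
  sims <- vapply(library$layer_names, function(nm) {
    ladj <- library$layers[[nm]]$adjacency
    el <- edge_keys(ladj)
    if (metric == "jaccard") {
      if (!length(eq) && !length(el)) 1
      else length(intersect(eq, el)) / length(union(eq, el))
    } else {
      sum(qadj == 1L & ladj == 1L) / (n * (n - 1L))
    }
  }, numeric(1))
  ord2 <- order(-sims, library$layer_names)
  data.frame(layer_name = library$layer_names[ord2],
             similarity = unname(sims[ord2]),
             stringsAsFactors = FALSE)
}
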