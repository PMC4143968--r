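#' Gene set collection over a fixed universe
#'
#' Flat, named gene sets (GMT semantics — no hierarchy) over an explicit
#' background universe. The universe plays the role of "all genes on the
#' array": every over-representation test in this module conditions on it.
#'
#' @param universe Character vector of unique gene identifiers.
#' @param sets Named list of character vectors, each a subset of
#'   `universe`; empty sets and duplicate names are rejected.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(universe, sets) {
  universe <- as.character(universe)
  if (!length(universe)) stop("empty universe")
  if (anyDuplicated(universe)) stop("universe contains duplicate gene ids")
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list of gene vectors")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) stop("empty gene sets: ", paste(names(sets)[empty], collapse = ", "))
  for (nm in names(sets)) {
    stray <- setdiff(sets[[nm]], universe)
    if (length(stray)) {
      stop("set ", nm, " contains genes outside the universe: ",
           paste(utils::head(stray, 5), collapse = ", "))
    }
  }
  structure(list(universe = universe, sets = sets),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over %d genes (sizes %d-%d)\n",
              length(x$sets), length(x$universe),
              min(vapply(x$sets, length, integer(1))),
              max(vapply(x$sets, length, integer(1)))))
  invisible(x)
}

#' Convert a synthetic gene universe to a collection
#' @param gu A [generate_gene_universe()] result.
#' @return A [gene_set_collection()].
#' @export
as_gene_set_collection <- function(gu) {
  stopifnot(inherits(gu, "gene_universe"))
  gene_set_collection(gu$genes, gu$sets)
}

#' Per-set over-representation of differentially expressed genes
#'
#' One-sided Fisher exact test of DE excess in each set: with `N` genes in
#' the universe, `K` in the set, `n` DE genes and `k` DE genes in the set,
#' the p-value is the hypergeometric upper tail `P(X >= k)`. Benjamini–
#' Hochberg q-values are computed across all sets of the collection. DE
#' genes outside the universe are dropped with a warning reporting the
#' count.
#'
#' @param collection A [gene_set_collection()].
#' @param de_genes Character vector of DE gene ids.
#' @return Data frame with one row per set: `set_name`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`, ordered by `p_value`.
#' @export
#' @examples
#' gsc <- gene_set_collection(letters, list(A = letters[1:6], B = letters[5:10]))
#' enrich_sets(gsc, c("a", "b", "c", "f"))
enrich_sets <- function(collection, de_genes) {
  stopifnot(inherits(collection, "gene_set_collection"))
  de_genes <- unique(as.character(de_genes))
  stray <- setdiff(de_genes, collection$universe)
  if (length(stray)) {
    warning(length(stray), " DE gene(s) not in the universe were dropped")
    de_genes <- setdiff(de_genes, stray)
  }
  N <- length(collection$universe)
  n <- length(de_genes)
  res <- data.frame(
    set_name = names(collection$sets),
    k = vapply(collection$sets, function(s) length(intersect(s, de_genes)), integer(1)),
    K = vapply(collection$sets, length, integer(1)),
    n = n, N = N,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$p_value <- hyper_upper_tail(res$k, res$K, res$n, res$N)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set_name), , drop = FALSE]
}

# P(X >= k) for X ~ Hypergeometric(N, K, n); vectorised, exact at k = 0 (p = 1)
hyper_upper_tail <- function(k, K, n, N) {
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Pathway-pair intersection enrichment network
#'
#' The pathway-level extension of over-representation analysis: instead of
#' scoring single sets, every unordered pair of sets whose intersection
#' has at least `min_intersection` genes is tested for DE excess *in the
#' intersection*, treating the intersection itself as a gene set against
#' the whole universe (hypergeometric upper tail on `(N, |I|, n, k_I)`).
#' P-values are BH-corrected across all tested pairs and an edge is drawn
#' when `q <= alpha`. Each edge carries its interface genes — the shared
#' members through which perturbations can propagate between the two
#' pathways — with DE members flagged. Nodes carry the per-set
#' [enrich_sets()] results.
#'
#' @param collection A [gene_set_collection()] with >= 2 sets.
#' @param de_genes DE gene ids.
#' @param alpha FDR level for drawing an edge.
#' @param min_intersection Minimum intersection size to test (pairs below
#'   it, including disjoint pairs, are skipped, not counted as tests).
#' @return An object of class `pathway_network`: `nodes` (enrichment data
#'   frame), `tests` (all tested pairs with `intersection_size`, `k_I`,
#'   `p_value`, `q_value`, `edge` flag), `edges` (significant subset),
#'   `interface` (named list, `"A|B"` -> data frame `gene`, `de`),
#'   `alpha`, `min_intersection`.
#' @export
intersection_network <- function(collection, de_genes, alpha = 0.05,
                                 min_intersection = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) < 2L) stop("need at least 2 sets to build a pathway network")
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  min_intersection <- as.integer(min_intersection)
  if (min_intersection < 1L) stop("`min_intersection` must be >= 1")
  nodes <- enrich_sets(collection, de_genes)
  de_genes <- intersect(unique(as.character(de_genes)), collection$universe)
  N <- length(collection$universe)
  n <- length(de_genes)
  set_names <- names(collection$sets)
  pairs <- utils::combn(set_names, 2L)
  rows <- list()
  interface <- list()
  for (c_idx in seq_len(ncol(pairs))) {
    a <- pairs[1, c_idx]; b <- pairs[2, c_idx]
    inter <- sort(intersect(collection$sets[[a]], collection$sets[[b]]))
    if (length(inter) < min_intersection) next
    k_I <- length(intersect(inter, de_genes))
    rows[[length(rows) + 1L]] <- data.frame(
      set_a = a, set_b = b, intersection_size = length(inter),
      k_I = k_I,
      p_value = hyper_upper_tail(k_I, length(inter), n, N),
      stringsAsFactors = FALSE
    )
    interface[[paste(a, b, sep = "|")]] <- data.frame(
      gene = inter, de = inter %in% de_genes, stringsAsFactors = FALSE
    )
  }
  tests <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(set_a = character(0), set_b = character(0),
               intersection_size = integer(0), k_I = integer(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  }
  tests$q_value <- if (nrow(tests)) stats::p.adjust(tests$p_value, "BH") else numeric(0)
  tests$edge <- tests$q_value <= alpha & nrow(tests) > 0
  edges <- tests[tests$edge, , drop = FALSE]
  structure(list(nodes = nodes, tests = tests, edges = edges,
                 interface = interface, alpha = alpha,
                 min_intersection = min_intersection),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network> %d pathways, %d pairs tested, %d edge(s) at FDR %.3g\n",
              nrow(x$nodes), nrow(x$tests), nrow(x$edges), x$alpha))
  invisible(x)
}

#' Interface genes of a pathway pair
#'
#' The sorted intersection of two gene sets with a flag marking DE
#' members: the shared elements through which signalling imbalance can
#' affect both biological functions.
#'
#' @param collection A [gene_set_collection()].
#' @param set_a,set_b Set names.
#' @param de_genes Optional DE gene ids for flagging.
#' @return Data frame `gene`, `de`, sorted by gene id (deterministic).
#' @export
interface_genes <- function(collection, set_a, set_b, de_genes = character(0)) {
  stopifnot(inherits(collection, "gene_set_collection"))
  for (nm in c(set_a, set_b)) {
    if (!nm %in% names(collection$sets)) stop("unknown set name \"", nm, "\"")
  }
  inter <- sort(intersect(collection$sets[[set_a]], collection$sets[[set_b]]))
  data.frame(gene = inter, de = inter %in% as.character(de_genes),
             stringsAsFactors = FALSE)
}

#' Export a pathway network to GraphML
#'
#' Nodes carry their per-set q-value; edges carry intersection size, DE
#' count in the intersection, and q-value.
#'
#' @param pn An [intersection_network()] result.
#' @param path Output GraphML file.
#' @return `path`, invisibly.
#' @export
write_pathway_graphml <- function(pn, path) {
  stopifnot(inherits(pn, "pathway_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(pn$nodes),
                            name = pn$nodes$set_name,
                            q_value = pn$nodes$q_value)
  if (nrow(pn$edges)) {
    ends <- rbind(pn$edges$set_a, pn$edges$set_b)
    g <- igraph::add_edges(g, as.vector(ends),
                           intersection_size = pn$edges$intersection_size,
                           k_I = pn$edges$k_I,
                           q_value = pn$edges$q_value)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
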