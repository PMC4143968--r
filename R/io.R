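#' Read a GMT gene-set file
#'
#' Strict GMT: one set per line, tab-separated fields `name`, `description`,
#' then gene ids. Lines with fewer than three fields, duplicate set names,
#' or (when a universe is supplied) genes outside it are parse errors
#' reporting the line number — whitespace-delimited look-alikes are
#' rejected rather than guessed at.
#'
#' @param path GMT file.
#' @param universe Optional explicit background universe; defaults to the
#'   union of all genes in the file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("parse error in ", path, ": no records")
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("parse error in ", path, " line ", i,
           ": expected >= 3 tab-separated fields (name, description, genes...)")
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      stop("parse error in ", path, " line ", i, ": duplicate set name \"", nm, "\"")
    }
    genes <- fields[-(1:2)]
    if (any(grepl("[[:space:]]", genes))) {
      stop("parse error in ", path, " line ", i,
           ": gene ids contain whitespace (GMT must be strictly tab-separated)")
    }
    sets[[nm]] <- genes
  }
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  gene_set_collection(universe, sets)
}

#' Write a gene-set collection (or synthetic universe) to GMT
#'
#' @param x A [gene_set_collection()] or [generate_gene_universe()] result.
#' @param path Output file.
#' @param descriptions Optional named descriptions; defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path, descriptions = NULL) {
  sets <- if (inherits(x, "gene_universe")) x$sets else {
    stopifnot(inherits(x, "gene_set_collection"))
    x$sets
  }
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write one-gene-per-line DE lists
#'
#' @param path File path.
#' @return `read_de_list` returns a character vector (blank lines
#'   dropped, duplicates rejected).
#' @export
read_de_list <- function(path) {
  if (!file.exists(path)) stop("DE list not found: ", path)
  genes <- readLines(path)
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) {
    stop("parse error in ", path, ": duplicate gene ids in DE list")
  }
  genes
}

#' @rdname read_de_list
#' @param genes Character vector of gene ids.
#' @export
write_de_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read / write a labelled similarity matrix as CSV
#'
#' First column and header row hold feature labels; values are written
#' with 17 significant digits so doubles round-trip exactly.
#'
#' @param sim A [similarity_matrix()].
#' @param path CSV file.
#' @param method Method tag to attach on read.
#' @return `read_similarity_csv` returns a [similarity_matrix()].
#' @export
write_similarity_csv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  write_labelled_matrix(sim$values, path, digits17 = TRUE)
}

#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path, method = "pearson") {
  m <- read_labelled_matrix(path)
  similarity_matrix(m, method = method)
}

#' Read / write a layer network as labelled adjacency CSV
#'
#' @param net A [layer_network()].
#' @param path CSV file.
#' @param threshold,mode,state_label Metadata to attach on read (the CSV
#'   stores the adjacency only).
#' @return `read_adjacency_csv` returns a [layer_network()].
#' @export
write_adjacency_csv <- function(net, path) {
  stopifnot(inherits(net, "layer_network"))
  write_labelled_matrix(net$adjacency, path, digits17 = FALSE)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path, threshold = NA_real_, mode = "signed",
                               state_label = "") {
  m <- read_labelled_matrix(path)
  if (!all(m %in% c(0, 1))) stop("parse error in ", path, ": adjacency entries must be 0/1")
  storage.mode(m) <- "integer"
  layer_network(m, threshold = threshold, mode = mode,
                state_label = state_label)
}

write_labelled_matrix <- function(m, path, digits17 = TRUE) {
  labs <- rownames(m)
  header <- paste(c("", labs), collapse = ",")
  fmt <- if (digits17) function(v) sprintf("%.17g", v) else function(v) format(v, scientific = FALSE)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(labs[i], fmt(m[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

read_labelled_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("parse error in ", path, ": matrix is not square")
  if (!identical(labs, colnames(m))) {
    stop("parse error in ", path, ": row and column labels disagree")
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Read / write a layer as a two-column edge list
#'
#' Tab-separated `from`/`to` pairs with a header line. Reading requires
#' the declared node label set so isolated nodes survive the round trip;
#' an edge naming an unknown label is a parse error.
#'
#' @param net A [layer_network()].
#' @param path Edge-list file.
#' @param node_labels Declared node set for reading.
#' @param threshold,mode,state_label Metadata to attach on read.
#' @return `read_edge_list` returns a [layer_network()].
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "layer_network"))
  e <- network_edges(net)
  writeLines(c("from\tto", if (nrow(e)) paste(e[, 1], e[, 2], sep = "\t")), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, node_labels, threshold = NA_real_,
                           mode = "signed", state_label = "") {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "from\tto") {
    stop("parse error in ", path, " line 1: expected header \"from\\tto\"")
  }
  node_labels <- as.character(node_labels)
  n <- length(node_labels)
  adj <- matrix(0L, n, n, dimnames = list(node_labels, node_labels))
  body <- lines[-1]
  body <- body[nzchar(body)]
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L) {
      stop("parse error in ", path, " line ", i + 1L, ": expected 2 fields")
    }
    unknown <- setdiff(fields, node_labels)
    if (length(unknown)) {
      stop("parse error in ", path, " line ", i + 1L,
           ": unknown node label(s): ", paste(unknown, collapse = ", "))
    }
    adj[fields[1], fields[2]] <- 1L
    adj[fields[2], fields[1]] <- 1L
  }
  layer_network(adj, threshold = threshold, mode = mode,
                state_label = state_label)
}

#' Export a layer network to GraphML
#'
#' @param net A [layer_network()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_layer_graphml <- function(net, path) {
  stopifnot(inherits(net, "layer_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a layer network to an igraph graph
#' @param net A [layer_network()].
#' @return An undirected `igraph` graph with named vertices.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "layer_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Connected-component membership of a layer network
#'
#' Used to compare a recovered network against a planted block partition.
#'
#' @param net A [layer_network()].
#' @return Integer vector of component ids, one per node.
#' @export
network_components <- function(net) {
  comp <- igraph::components(as_igraph(net))
  as.integer(comp$membership)
}
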