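#' Validate a pipeline configuration
#'
#' A pipeline run is described by a declarative config (a named list, or a
#' YAML file read with [read_pipeline_config()]). Unknown keys are
#' rejected and every value is range-checked before any computation, so a
#' typo cannot silently change an analysis.
#'
#' Recognised keys: `inputs` (named list/vector of feature-table paths,
#' names become layer names), `delimiter`, `method`
#' (`pearson`/`spearman`/`partial`), `shrinkage`, `threshold`, `mode`
#' (`signed`/`absolute`), `sweep` (`list(min, max, step)`, optional),
#' `nperm` + `null_mode` (optional permutation validation), `seed`,
#' `out_dir`.
#'
#' @param config Named list.
#' @return The config with defaults filled in, invisibly usable by
#'   [run_pipeline()].
#' @export
validate_pipeline_config <- function(config) {
  known <- c("inputs", "delimiter", "method", "shrinkage", "threshold",
             "mode", "sweep", "nperm", "null_mode", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(delimiter = "\t", method = "pearson", shrinkage = "auto",
                   threshold = 0.8, mode = "signed", sweep = NULL,
                   nperm = NULL, null_mode = "shuffle", seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  }
  if (is.null(config$inputs) || !length(config$inputs)) {
    stop("config field `inputs` must list at least one recording")
  }
  inputs <- unlist(config$inputs)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    stop("config field `inputs` entries must be named (layer names)")
  }
  if (anyDuplicated(names(inputs))) stop("config field `inputs` has duplicate layer names")
  config$inputs <- inputs
  config$method <- match.arg(config$method, c("pearson", "spearman", "partial"))
  config$mode <- match.arg(config$mode, c("signed", "absolute"))
  thr <- as.numeric(config$threshold)
  lo <- if (config$mode == "absolute") 0 else -1
  if (is.na(thr) || thr <= lo || thr >= 1) {
    stop("config field `threshold` out of range (", lo, ", 1): got ", config$threshold)
  }
  config$threshold <- thr
  if (!is.null(config$sweep)) {
    sw <- config$sweep
    if (!all(c("min", "max", "step") %in% names(sw))) {
      stop("config field `sweep` needs min, max, step")
    }
    if (!(sw$min < sw$max) || sw$step <= 0) {
      stop("config field `sweep` is not a valid range")
    }
  }
  if (!is.null(config$nperm)) {
    if (as.integer(config$nperm) < 1L) stop("config field `nperm` must be >= 1")
    config$null_mode <- match.arg(config$null_mode, c("shuffle", "phase_shift"))
  }
  config$seed <- as.integer(config$seed)
  if (is.null(config$out_dir)) stop("config field `out_dir` is required")
  config
}

#' Read a pipeline config from YAML
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the reconstruction-to-multiplex pipeline
#'
#' End-to-end driver: reads every input recording, computes its similarity
#' matrix and coefficient histogram, thresholds it into a layer (plus an
#' optional threshold sweep and permutation validation), assembles the
#' multiplex, and writes the pairwise overlap report and layer-similarity
#' matrices. All inputs are checked before any computation; outputs are
#' deterministic given the config and seed, and a machine-readable
#' manifest (resolved config, package version, md5 of every artifact) is
#' written last so a complete run can be distinguished from an interrupted
#' one.
#'
#' @param config Named list or path to a YAML config (see
#'   [validate_pipeline_config()]).
#' @return The manifest, invisibly; artifacts go to `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  } else {
    config <- validate_pipeline_config(config)
  }
  missing <- config$inputs[!file.exists(config$inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  layers <- list()
  for (nm in names(config$inputs)) {
    ts <- read_feature_timeseries(config$inputs[[nm]],
                                  delimiter = config$delimiter,
                                  state_label = nm)
    sim <- if (config$method == "partial") {
      compute_partial_correlation(ts, shrinkage = config$shrinkage)
    } else {
      compute_similarity(ts, method = config$method)
    }
    f_sim <- file.path(out_dir, paste0("similarity_", nm, ".csv"))
    write_similarity_csv(sim, f_sim)
    hist_df <- summarize_coefficients(sim)
    f_hist <- file.path(out_dir, paste0("coefficient_hist_", nm, ".csv"))
    utils::write.csv(hist_df, f_hist, row.names = FALSE)
    net <- threshold_network(sim, config$threshold, mode = config$mode,
                             state_label = nm)
    f_adj <- file.path(out_dir, paste0("network_", nm, "_adjacency.csv"))
    f_edges <- file.path(out_dir, paste0("network_", nm, "_edges.tsv"))
    write_adjacency_csv(net, f_adj)
    write_edge_list(net, f_edges)
    artifacts <- c(artifacts, f_sim, f_hist, f_adj, f_edges)
    if (!is.null(config$sweep)) {
      sw <- threshold_sweep(sim, config$sweep$min, config$sweep$max,
                            config$sweep$step, mode = config$mode)
      f_sw <- file.path(out_dir, paste0("sweep_", nm, ".csv"))
      utils::write.csv(as.data.frame(sw), f_sw, row.names = FALSE)
      artifacts <- c(artifacts, f_sw)
    }
    if (!is.null(config$nperm)) {
      ls <- permutation_null(ts, n_permutations = as.integer(config$nperm),
                             null_mode = config$null_mode,
                             seed = config$seed + match(nm, names(config$inputs)))
      f_p <- file.path(out_dir, paste0("link_pvalues_", nm, ".csv"))
      write_labelled_matrix(ls$p_values, f_p, digits17 = TRUE)
      artifacts <- c(artifacts, f_p)
    }
    layers[[nm]] <- net
  }
  if (length(layers) >= 2L) {
    mx <- build_multiplex(unname(layers), layer_names = names(layers))
    pairs <- utils::combn(names(layers), 2L)
    report <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(ci) {
      ov <- layer_overlap(mx, pairs[1, ci], pairs[2, ci])
      data.frame(layer_a = pairs[1, ci], layer_b = pairs[2, ci],
                 shared_ordered_pairs = ov$shared_ordered_pairs,
                 possible_ordered_pairs = ov$possible_ordered_pairs,
                 overlap_fraction = ov$overlap_fraction,
                 jaccard = ov$jaccard, stringsAsFactors = FALSE)
    }))
    f_ov <- file.path(out_dir, "overlap_report.csv")
    utils::write.csv(report, f_ov, row.names = FALSE)
    f_deg <- file.path(out_dir, "degree_vectors.csv")
    utils::write.csv(as.data.frame(degree_vectors(mx)), f_deg)
    f_lsim <- file.path(out_dir, "layer_similarity_jaccard.csv")
    utils::write.csv(layer_similarity_matrix(mx, "jaccard"), f_lsim)
    artifacts <- c(artifacts, f_ov, f_deg, f_lsim)
  }
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    package = "brainplex",
    version = as.character(utils::packageVersion("brainplex")),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(artifacts)), basename(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
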