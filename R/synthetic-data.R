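#' State template: planted block-correlation structure
#'
#' A brain state is emulated as a partition of the features into blocks
#' that co-activate: features in the same block load on a shared latent
#' series, features in different blocks are independent. The default
#' `"contiguous"` layout places blocks of near-equal size side by side,
#' mimicking recordings where nearby features tend to become active
#' together; the `"interleaved"` layout assigns feature i to block
#' `i mod n_blocks`, producing a partition that (for equal block counts)
#' shares no co-blocked pair with the contiguous one — a convenient
#' maximally-different second state.
#'
#' @param n_features Number of features (default 121, the size of the
#'   recordings the pipeline was designed around).
#' @param n_blocks Number of co-activation blocks, between 1 and
#'   `n_features`.
#' @param rho_within Within-block latent loading in `[0, 1]`; with
#'   `noise_sd = 1` it equals the population correlation of two co-blocked
#'   features.
#' @param noise_sd Standard deviation of feature-private noise (>= 0).
#' @param layout `"contiguous"` or `"interleaved"` block arrangement.
#' @param seed Optional integer seed; the template construction is fully
#'   deterministic, the argument is kept so every generator in the package
#'   has an explicit seed slot.
#'
#' @return An object of class `state_template` with fields `n_features`,
#'   `block_assignment` (integer vector, feature index -> block id),
#'   `rho_within`, `noise_sd`, `layout`.
#' @export
#' @examples
#' tpl <- generate_state_template(12, 3, rho_within = 0.9)
#' table(tpl$block_assignment)
generate_state_template <- function(n_features = 121, n_blocks,
                                    rho_within, noise_sd = 1,
                                    layout = c("contiguous", "interleaved"),
                                    seed = NULL) {
  layout <- match.arg(layout)
  n_features <- as.integer(n_features)
  n_blocks <- as.integer(n_blocks)
  if (n_features < 1L) stop("`n_features` must be positive")
  if (n_blocks < 1L || n_blocks > n_features) {
    stop("`n_blocks` must be between 1 and n_features (got ", n_blocks,
         " blocks for ", n_features, " features)")
  }
  if (rho_within < 0 || rho_within > 1) stop("`rho_within` must be in [0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  assignment <- switch(layout,
    contiguous = {
      # near-equal contiguous blocks: the first (n mod k) blocks get the
      # extra feature
      base <- n_features %/% n_blocks
      extra <- n_features %% n_blocks
      sizes <- rep(base, n_blocks) + c(rep(1L, extra), rep(0L, n_blocks - extra))
      rep(seq_len(n_blocks), times = sizes)
    },
    interleaved = (seq_len(n_features) - 1L) %% n_blocks + 1L
  )
  structure(
    list(n_features = n_features,
         block_assignment = as.integer(assignment),
         rho_within = as.numeric(rho_within),
         noise_sd = as.numeric(noise_sd),
         layout = layout),
    class = "state_template"
  )
}

#' @export
print.state_template <- function(x, ...) {
  cat(sprintf("<state_template> %d features in %d %s blocks, rho_within = %g, noise_sd = %g\n",
              x$n_features, max(x$block_assignment), x$layout,
              x$rho_within, x$noise_sd))
  invisible(x)
}

#' Fraction of feature pairs co-blocked in both of two templates
#'
#' Compares two partitions of the same feature set by the fraction of all
#' `n(n-1)/2` unordered pairs that sit in one block under both templates.
#' Zero means the two states share no planted co-activation pair.
#'
#' @param a,b `state_template` objects over the same number of features.
#' @return A fraction in `[0, 1]`.
#' @export
template_coblock_fraction <- function(a, b) {
  stopifnot(inherits(a, "state_template"), inherits(b, "state_template"))
  if (a$n_features != b$n_features) stop("templates cover different feature counts")
  same_a <- outer(a$block_assignment, a$block_assignment, "==")
  same_b <- outer(b$block_assignment, b$block_assignment, "==")
  both <- same_a & same_b
  n <- a$n_features
  (sum(both) - n) / (n * (n - 1))
}

#' Simulate a recording from a state template
#'
#' Latent block-factor model: feature i at time t is
#' `sqrt(rho) * z_b(t) + sqrt(1 - rho) * noise_sd * e_i(t)` with `z_b` a
#' standard latent series shared by block b and `e_i` independent standard
#' noise. With `noise_sd = 1` the population correlation of two co-blocked
#' features is exactly `rho_within` and cross-block correlations are 0; in
#' general the within-block correlation is
#' `rho / (rho + (1 - rho) * noise_sd^2)`. Latent and noise series are
#' i.i.d. Gaussian by default; `ar` adds AR(1) temporal smoothness (unit
#' marginal variance preserved) for experiments on autocorrelated nulls.
#'
#' @param template A [generate_state_template()] result.
#' @param n_timepoints Series length (>= 3).
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param ar AR(1) coefficient in `[0, 1)` applied to latent and noise
#'   series; 0 (default) gives white series.
#' @param state_label State label to stamp on the recording; defaults to
#'   the template layout.
#' @param feature_labels Optional custom labels.
#' @return A [feature_timeseries()].
#' @export
simulate_feature_timeseries <- function(template, n_timepoints, seed,
                                        ar = 0, state_label = NULL,
                                        feature_labels = NULL) {
  stopifnot(inherits(template, "state_template"))
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 3L) {
    stop("`n_timepoints` must be >= 3 (correlation is degenerate below that)")
  }
  if (ar < 0 || ar >= 1) stop("`ar` must be in [0, 1)")
  n <- template$n_features
  k <- max(template$block_assignment)
  vals <- withr::with_seed(seed, {
    z <- matrix(stats::rnorm(k * n_timepoints), nrow = k)
    e <- matrix(stats::rnorm(n * n_timepoints), nrow = n)
    if (ar > 0) {
      z <- ar1_smooth(z, ar)
      e <- ar1_smooth(e, ar)
    }
    sqrt(template$rho_within) * z[template$block_assignment, , drop = FALSE] +
      sqrt(1 - template$rho_within) * template$noise_sd * e
  })
  if (is.null(state_label)) state_label <- template$layout
  feature_timeseries(vals, feature_labels = feature_labels,
                     state_label = state_label)
}

# AR(1) filter with innovations rescaled so every marginal stays N(0, 1)
ar1_smooth <- function(x, phi) {
  out <- x
  out[, 1] <- x[, 1]
  for (t in 2:ncol(x)) {
    out[, t] <- phi * out[, t - 1] + sqrt(1 - phi^2) * x[, t]
  }
  out
}

#' Score recovery of a planted block partition
#'
#' Pairwise precision/recall of a predicted feature partition against the
#' planted one: a "positive" is an unordered feature pair placed in the
#' same group. Used to quantify how well thresholded networks recover the
#' simulated co-activation blocks.
#'
#' @param predicted Integer/character vector of predicted group memberships.
#' @param truth Integer vector of planted block ids (same length).
#' @return A list with `precision`, `recall`, and `exact` (TRUE when the
#'   two partitions are identical up to relabelling).
#' @export
score_partition_recovery <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("partition vectors differ in length")
  same_p <- outer(predicted, predicted, "==")
  same_t <- outer(truth, truth, "==")
  ut <- upper.tri(same_p)
  tp <- sum(same_p[ut] & same_t[ut])
  fp <- sum(same_p[ut] & !same_t[ut])
  fn <- sum(!same_p[ut] & same_t[ut])
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  list(precision = precision, recall = recall,
       exact = fp == 0L && fn == 0L)
}

#' Synthetic gene universe with controlled set overlaps and planted DE
#'
#' Builds a gene universe, named gene sets whose pairwise intersections hit
#' requested sizes exactly (overlap genes for a pair are drawn from the
#' earlier set's exclusive region so third-party overlaps stay at their own
#' targets), and a differentially-expressed (DE) gene list. An enrichment
#' plan oversamples DE genes in chosen sets or set intersections at a
#' planted odds ratio, giving downstream over-representation tests a known
#' ground truth; with an empty plan DE genes are drawn uniformly.
#'
#' @param n_genes Universe size.
#' @param set_sizes Named (or auto-named `S1`, `S2`, ...) integer vector of
#'   gene-set sizes, each `<= n_genes`.
#' @param overlap_fractions Either a single fraction applied to every set
#'   pair or a symmetric matrix of fractions; the target intersection of a
#'   pair is `round(frac * min(size_i, size_j))` genes.
#' @param n_de Number of DE genes (`<= n_genes`).
#' @param enrichment_plan `NULL`/empty for uniform DE, else a list of
#'   `list(sets = c(...), odds_ratio = r)` entries: genes in the
#'   intersection of the named sets get sampling weight `r` (> 1 plants an
#'   excess).
#' @param seed Integer seed.
#' @return An object of class `gene_universe`: `genes`, `sets` (named list
#'   of character vectors), `de_genes`, `enrichment_plan`.
#' @export
generate_gene_universe <- function(n_genes, set_sizes,
                                   overlap_fractions = 0, n_de,
                                   enrichment_plan = NULL, seed) {
  n_genes <- as.integer(n_genes)
  set_names <- names(set_sizes)
  set_sizes <- as.integer(set_sizes)
  m <- length(set_sizes)
  if (any(set_sizes < 1L)) stop("set sizes must be positive")
  if (any(set_sizes > n_genes)) stop("a set size exceeds the universe size")
  if (n_de < 0L || n_de > n_genes) stop("`n_de` must be between 0 and n_genes")
  if (is.null(set_names)) set_names <- paste0("S", seq_len(m))
  if (anyDuplicated(set_names)) stop("set names must be unique")
  ov <- overlap_fractions
  if (length(ov) == 1L) {
    ov <- matrix(as.numeric(ov), m, m)
  }
  ov <- as.matrix(ov)
  if (!all(dim(ov) == c(m, m)) || any(abs(ov - t(ov)) > 1e-12)) {
    stop("`overlap_fractions` must be a scalar or a symmetric ", m, "x", m, " matrix")
  }
  diag(ov) <- 0
  if (any(ov < 0 | ov > 1)) stop("overlap fractions must be in [0, 1]")

  genes <- sprintf("g%0*d", max(5L, nchar(as.character(n_genes))), seq_len(n_genes))
  withr::with_seed(seed, {
    sets <- vector("list", m)
    names(sets) <- set_names
    in_any <- character(0)
    for (j in seq_len(m)) {
      members <- character(0)
      for (i in seq_len(j - 1L)) {
        target <- as.integer(round(ov[i, j] * min(set_sizes[i], set_sizes[j])))
        if (target == 0L) next
        # draw shared genes from set i's exclusive region so the overlap
        # with any third set is not disturbed
        exclusive_i <- setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE))
        exclusive_i <- setdiff(exclusive_i, members)
        if (length(exclusive_i) < target) {
          stop("infeasible overlap demand between sets ", set_names[i], " and ",
               set_names[j], ": need ", target, " exclusive genes of ",
               set_names[i], " but only ", length(exclusive_i), " remain")
        }
        members <- c(members, sample(exclusive_i, target))
      }
      fresh_needed <- set_sizes[j] - length(members)
      if (fresh_needed < 0L) {
        stop("overlap demands for set ", set_names[j],
             " exceed its size (", set_sizes[j], ")")
      }
      pool <- setdiff(genes, c(in_any, members))
      if (length(pool) < fresh_needed) {
        stop("infeasible set construction: universe too small for set ",
             set_names[j], " (need ", fresh_needed, " fresh genes, ",
             length(pool), " available)")
      }
      members <- c(members, sample(pool, fresh_needed))
      sets[[j]] <- sort(members)
      in_any <- union(in_any, members)
    }

    weights <- rep(1, n_genes)
    names(weights) <- genes
    if (length(enrichment_plan)) {
      for (entry in enrichment_plan) {
        if (is.null(entry$sets) || is.null(entry$odds_ratio)) {
          stop("each enrichment_plan entry needs `sets` and `odds_ratio`")
        }
        missing_sets <- setdiff(entry$sets, set_names)
        if (length(missing_sets)) {
          stop("enrichment_plan names unknown sets: ",
               paste(missing_sets, collapse = ", "))
        }
        region <- Reduce(intersect, sets[entry$sets])
        if (!length(region)) {
          stop("enrichment_plan targets an empty intersection of: ",
               paste(entry$sets, collapse = ", "))
        }
        weights[region] <- weights[region] * entry$odds_ratio
      }
    }
    de_genes <- if (n_de == 0L) character(0) else {
      sort(sample(genes, n_de, prob = weights))
    }
    structure(
      list(genes = genes, sets = sets, de_genes = de_genes,
           enrichment_plan = enrichment_plan),
      class = "gene_universe"
    )
  })
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe> %d genes, %d sets, %d DE genes, %d planted enrichment(s)\n",
              length(x$genes), length(x$sets), length(x$de_genes),
              length(x$enrichment_plan)))
  invisible(x)
}
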