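#' Construct a similarity matrix object
#'
#' Internal-facing constructor; users normally obtain these from
#' [compute_similarity()] or [compute_partial_correlation()].
#'
#' @param values Symmetric numeric matrix with entries in `[-1, 1]`.
#' @param method `"pearson"`, `"spearman"` or `"partial"`.
#' @param feature_labels Node labels, one per row.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, method, feature_labels = rownames(values)) {
  method <- match.arg(method, c("pearson", "spearman", "partial"))
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("`values` must be a square matrix")
  }
  if (is.null(feature_labels)) feature_labels <- default_feature_labels(nrow(values))
  feature_labels <- as.character(feature_labels)
  if (anyDuplicated(feature_labels)) stop("feature labels must be unique")
  if (max(abs(values - t(values))) > 1e-8) stop("similarity matrix is not symmetric")
  values <- (values + t(values)) / 2
  values <- pmin(pmax(values, -1), 1)
  dimnames(values) <- list(feature_labels, feature_labels)
  structure(list(values = values, method = method,
                 feature_labels = feature_labels),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<similarity_matrix> %s, %d features; off-diagonal range [%.3f, %.3f]\n",
              x$method, nrow(x$values), min(off), max(off)))
  invisible(x)
}

#' Whole-series correlation between features
#'
#' Correlates every pair of feature series over the whole recording (no
#' windowing by default) and returns the full symmetric coefficient
#' matrix. Optionally a sliding window can be supplied, in which case the
#' reported coefficient for a pair is the mean over windows — useful for
#' checking stability of the whole-series estimate, not the default
#' because the analysis targets state-level (whole recording) structure.
#'
#' @param ts A [feature_timeseries()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param window Optional window length in time points; `NULL` correlates
#'   the whole series.
#' @param stride Window stride when `window` is given.
#' @return A [similarity_matrix()] with the chosen method.
#' @export
#' @examples
#' tpl <- generate_state_template(10, 2, rho_within = 0.8)
#' ts <- simulate_feature_timeseries(tpl, 200, seed = 1)
#' sim <- compute_similarity(ts)
compute_similarity <- function(ts, method = c("pearson", "spearman"),
                               window = NULL, stride = 1) {
  stopifnot(inherits(ts, "feature_timeseries"))
  method <- match.arg(method)
  x <- ts$values
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(ts$feature_labels[sds == 0], collapse = ", "))
  }
  if (is.null(window)) {
    r <- stats::cor(t(x), method = method)
  } else {
    window <- as.integer(window)
    stride <- as.integer(stride)
    if (window < 3L || window > ncol(x)) stop("`window` must be in [3, n_timepoints]")
    if (stride < 1L) stop("`stride` must be >= 1")
    starts <- seq(1L, ncol(x) - window + 1L, by = stride)
    acc <- matrix(0, nrow(x), nrow(x))
    for (s in starts) {
      acc <- acc + stats::cor(t(x[, s:(s + window - 1L), drop = FALSE]),
                              method = method)
    }
    r <- acc / length(starts)
  }
  diag(r) <- 1
  similarity_matrix(r, method = method, feature_labels = ts$feature_labels)
}

#' Shrinkage partial correlation (Gaussian graphical model)
#'
#' Partial correlations are read off the inverse of the correlation
#' matrix: `p_ij = -w_ij / sqrt(w_ii * w_jj)` with `W = R^-1`. When the
#' number of features approaches or exceeds the number of time points the
#' sample correlation matrix is singular, so `R` is first blended toward
#' the identity, `R(lambda) = (1 - lambda) R + lambda I`. The default
#' `shrinkage = "auto"` plugs in the analytic variance-minimising
#' intensity `lambda* = sum Var(r_ij) / sum r_ij^2` over off-diagonal
#' entries (clamped to `[0, 1]`), so no cross-validation is needed.
#'
#' @param ts A [feature_timeseries()].
#' @param shrinkage `"auto"` or a fraction in `[0, 1]`. `0` attempts a raw
#'   inversion and fails with advice when the matrix is singular; `1`
#'   returns zero off-diagonal partial correlations.
#' @return A [similarity_matrix()] with method `"partial"`; the shrinkage
#'   intensity actually used is attached as attribute `"shrinkage"`.
#' @export
compute_partial_correlation <- function(ts, shrinkage = "auto") {
  stopifnot(inherits(ts, "feature_timeseries"))
  x <- ts$values
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(ts$feature_labels[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(x))
  lambda <- if (identical(shrinkage, "auto")) {
    shrinkage_intensity(x)
  } else {
    lam <- as.numeric(shrinkage)
    if (is.na(lam) || lam < 0 || lam > 1) stop("`shrinkage` must be \"auto\" or in [0, 1]")
    lam
  }
  r_sh <- (1 - lambda) * r
  diag(r_sh) <- 1
  w <- tryCatch(
    solve(r_sh),
    error = function(e) {
      stop("correlation matrix could not be inverted at shrinkage = ",
           signif(lambda, 4),
           "; use a nonzero shrinkage (or shrinkage = \"auto\")", call. = FALSE)
    }
  )
  d <- sqrt(diag(w))
  p <- -w / tcrossprod(d)
  diag(p) <- 1
  out <- similarity_matrix(p, method = "partial",
                           feature_labels = ts$feature_labels)
  attr(out, "shrinkage") <- lambda
  out
}

# analytic variance-minimising shrinkage intensity toward the identity:
# lambda* = sum_ij Var-hat(r_ij) / sum_ij r_ij^2 over i != j
shrinkage_intensity <- function(x) {
  n <- ncol(x)  # time points
  xs <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
  wbar <- tcrossprod(xs) / n           # mean_t of w_ijt = xs_it * xs_jt
  sw2 <- tcrossprod(xs^2)              # sum_t of w_ijt^2
  r <- n / (n - 1) * wbar
  var_r <- n / (n - 1)^3 * (sw2 - n * wbar^2)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  if (denom == 0) return(1)
  min(1, max(0, sum(var_r[off]) / denom))
}

#' Histogram of off-diagonal similarity coefficients
#'
#' Summarises the distribution of coefficients over the `n(n-1)/2`
#' unordered feature pairs (each pair counted once, diagonal excluded),
#' on fixed equal-width bins spanning `[-1, 1]` so histograms from
#' different recordings are directly comparable.
#'
#' @param sim A [similarity_matrix()].
#' @param bins Number of bins over `[-1, 1]`.
#' @return A data frame with columns `lower`, `upper`, `count`; the total
#'   count equals `n(n-1)/2`.
#' @export
summarize_coefficients <- function(sim, bins = 40) {
  stopifnot(inherits(sim, "similarity_matrix"))
  bins <- as.integer(bins)
  if (bins < 1L) stop("`bins` must be >= 1")
  v <- sim$values[upper.tri(sim$values)]
  breaks <- seq(-1, 1, length.out = bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE, include.lowest = TRUE,
                      right = TRUE)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L],
             count = h$counts)
}
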