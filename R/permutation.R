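#' Permutation / surrogate significance of correlation links
#'
#' Attaches a p-value to every feature pair by comparing the observed
#' absolute correlation to a null ensemble in which the temporal alignment
#' between series is destroyed while each series' own values are kept:
#'
#' * `"shuffle"` — every feature's series is independently randomly
#'   permuted in each null draw, so each pair compares two independently
#'   shuffled series (equivalent in distribution to permuting one series
#'   of the pair);
#' * `"phase_shift"` — every series is circularly rotated by an
#'   independent lag drawn uniformly from `1..T-1`, preserving each
#'   series' autocorrelation while breaking cross-series alignment.
#'
#' P-values use the add-one estimator
#' `p = (1 + #\{null |r| >= observed |r|\}) / (n_permutations + 1)`, so the
#' smallest attainable value is `1/(n_permutations + 1)` and the values
#' are valid (never anti-conservative) at any permutation count.
#'
#' @param ts A [feature_timeseries()].
#' @param n_permutations Number of null draws (>= 1).
#' @param null_mode `"shuffle"` or `"phase_shift"`.
#' @param seed Integer seed for the null ensemble.
#' @return An object of class `link_significance`: `p_values` (symmetric
#'   matrix, diagonal 1), `n_permutations`, `null_mode`.
#' @export
permutation_null <- function(ts, n_permutations = 999,
                             null_mode = c("shuffle", "phase_shift"), seed) {
  stopifnot(inherits(ts, "feature_timeseries"))
  null_mode <- match.arg(null_mode)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1")
  x <- ts$values
  n <- nrow(x)
  tt <- ncol(x)
  obs <- abs(stats::cor(t(x)))
  count <- matrix(0L, n, n)
  withr::with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      xb <- switch(null_mode,
        shuffle = {
          out <- x
          for (i in seq_len(n)) out[i, ] <- x[i, sample.int(tt)]
          out
        },
        phase_shift = {
          lags <- sample.int(tt - 1L, n, replace = TRUE)
          out <- x
          for (i in seq_len(n)) {
            l <- lags[i]
            out[i, ] <- x[i, c((l + 1L):tt, 1L:l)]
          }
          out
        }
      )
      rb <- abs(stats::cor(t(xb)))
      count <- count + (rb >= obs)
    }
  })
  p <- (1 + count) / (n_permutations + 1)
  # the diagonal compares |r|=1 against |r|=1 in every draw, giving p = 1
  dimnames(p) <- list(ts$feature_labels, ts$feature_labels)
  structure(list(p_values = p, n_permutations = n_permutations,
                 null_mode = null_mode),
            class = "link_significance")
}

#' @export
print.link_significance <- function(x, ...) {
  off <- x$p_values[upper.tri(x$p_values)]
  cat(sprintf("<link_significance> %s null, %d permutations, %d pairs; min p = %.4g\n",
              x$null_mode, x$n_permutations, length(off), min(off)))
  invisible(x)
}

#' FDR-adjust link p-values
#'
#' Benjamini–Hochberg correction over the `n(n-1)/2` unordered pairs.
#'
#' @param ls A [permutation_null()] result.
#' @return `ls` with an added symmetric `q_values` matrix (diagonal 1).
#' @export
adjust_link_significance <- function(ls) {
  stopifnot(inherits(ls, "link_significance"))
  p <- ls$p_values
  ut <- upper.tri(p)
  q <- p
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 1
  ls$q_values <- q
  ls
}
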