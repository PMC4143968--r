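#' Feature-by-time recording
#'
#' Container for a single recording: a numeric matrix with one row per
#' extracted activity feature and one column per time point, plus a label
#' describing the brain state the recording was taken in (e.g. `"sleep-A"`,
#' `"dream"`). All downstream network reconstruction operates on this
#' object; the similarity step correlates rows over the whole series.
#'
#' @param values Numeric matrix, features in rows, time points in columns.
#'   Must have at least 2 rows and 3 columns and contain no missing values.
#' @param feature_labels Character vector of unique feature names, one per
#'   row. Defaults to the rownames of `values`, or `F001`, `F002`, ... when
#'   those are absent.
#' @param state_label Free-text label of the recorded state.
#' @param dt Sampling interval in seconds (metadata only; the analysis is
#'   invariant to it).
#'
#' @return An object of class `feature_timeseries` with elements `values`,
#'   `feature_labels`, `state_label` and `dt`.
#' @export
#' @examples
#' ts <- feature_timeseries(matrix(rnorm(20), nrow = 4), state_label = "wake")
#' dim(ts$values)
feature_timeseries <- function(values, feature_labels = NULL,
                               state_label = "", dt = 1) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x time)")
  }
  if (nrow(values) < 2L) stop("a recording needs at least 2 features")
  if (ncol(values) < 3L) stop("a recording needs at least 3 time points")
  if (anyNA(values)) stop("`values` contains missing entries; clean or impute before construction")
  if (is.null(feature_labels)) {
    feature_labels <- rownames(values)
    if (is.null(feature_labels)) {
      feature_labels <- default_feature_labels(nrow(values))
    }
  }
  feature_labels <- as.character(feature_labels)
  if (length(feature_labels) != nrow(values)) {
    stop("`feature_labels` must have one entry per feature row")
  }
  if (anyDuplicated(feature_labels)) {
    stop("feature labels must be unique; duplicated: ",
         paste(unique(feature_labels[duplicated(feature_labels)]), collapse = ", "))
  }
  rownames(values) <- feature_labels
  colnames(values) <- NULL
  structure(
    list(values = values, feature_labels = feature_labels,
         state_label = as.character(state_label)[1], dt = as.numeric(dt)[1]),
    class = "feature_timeseries"
  )
}

default_feature_labels <- function(n) {
  sprintf("F%0*d", max(3L, nchar(as.character(n))), seq_len(n))
}

#' @export
print.feature_timeseries <- function(x, ...) {
  cat(sprintf("<feature_timeseries> %d features x %d time points, state = \"%s\", dt = %gs\n",
              nrow(x$values), ncol(x$values), x$state_label, x$dt))
  invisible(x)
}

#' Read a feature-by-time table
#'
#' Reads the tabular dialect written by [write_feature_timeseries()]: a
#' header row of time indices, then one row per feature whose first field
#' is the feature label. Missing cells either abort the read or are imputed
#' by the feature's row mean, controlled by `na_action` — there is no
#' silent default handling.
#'
#' @param path File to read.
#' @param delimiter Field separator; tab by default, use `","` for CSV.
#' @param state_label State label to attach (the file stores none).
#' @param dt Sampling interval in seconds.
#' @param na_action `"error"` (default) or `"impute_mean"`.
#' @return A [feature_timeseries()] object.
#' @export
read_feature_timeseries <- function(path, delimiter = "\t", state_label = "",
                                    dt = 1, na_action = c("error", "impute_mean")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("parse error in ", path, ": need a label column plus >= 3 time points")
  labels <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    if (na_action == "error") {
      bad <- which(rowSums(is.na(vals)) > 0L)
      stop("missing values in features: ", paste(labels[bad], collapse = ", "),
           " (use na_action = \"impute_mean\" to impute)")
    }
    for (i in seq_len(nrow(vals))) {
      miss <- is.na(vals[i, ])
      if (all(miss)) stop("feature ", labels[i], " is entirely missing; cannot impute")
      vals[i, miss] <- mean(vals[i, !miss])
    }
  }
  feature_timeseries(vals, feature_labels = labels,
                     state_label = state_label, dt = dt)
}

#' Write a feature-by-time table
#'
#' Tab-separated by default: header of time indices, first column the
#' feature label. Numbers are written with 17 significant digits so a
#' read/write/read cycle reproduces the doubles exactly.
#'
#' @param ts A [feature_timeseries()].
#' @param path Output file.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_feature_timeseries <- function(ts, path, delimiter = "\t") {
  stopifnot(inherits(ts, "feature_timeseries"))
  header <- paste(c("feature", seq_len(ncol(ts$values))), collapse = delimiter)
  rows <- vapply(seq_len(nrow(ts$values)), function(i) {
    paste(c(ts$feature_labels[i], sprintf("%.17g", ts$values[i, ])),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
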