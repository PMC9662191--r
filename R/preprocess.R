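#' Autoscale a feature table
#'
#' Standardizes every feature to mean 0 and sample standard deviation 1
#' (n-1 denominator), the "auto scaling" normalization applied to all
#' layers before modelling. Zero-variance features cannot be scaled and are
#' dropped with a warning.
#'
#' @param table a [feature_table()] with at least 2 samples.
#' @return A [feature_table()] with `value_kind = "normalized"`.
#' @export
autoscale <- function(table) {
  x <- table$values
  if (nrow(x) < 2) stop("autoscale needs at least 2 samples")
  sds <- apply(x, 2L, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (all(drop)) stop("all features have zero variance; nothing to autoscale")
  if (any(drop))
    warning("autoscale: dropped ", sum(drop), " zero-variance feature(s): ",
            paste(utils::head(colnames(x)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
  x <- x[, !drop, drop = FALSE]
  x <- scale(x, center = TRUE, scale = TRUE)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  feature_table(unclass(x), layer = table$layer, value_kind = "normalized")
}

#' Remove sparse features
#'
#' Drops features whose value is nonzero in fewer than `min_prevalence`
#' of the samples; used for the advanced-adenoma sub-analysis where very
#' sparse, skewed taxa are excluded before testing.
#'
#' @param table a [feature_table()].
#' @param min_prevalence required fraction of samples with a nonzero value,
#'   in `[0, 1]`.
#' @return A filtered [feature_table()]; removals are reported via `message()`.
#' @export
filter_sparse_features <- function(table, min_prevalence) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  prev <- colMeans(table$values != 0)
  drop <- prev < min_prevalence
  if (any(drop))
    message("filter_sparse_features: removed ", sum(drop), " feature(s) below prevalence ",
            min_prevalence, ": ", paste(utils::head(colnames(table$values)[drop], 8), collapse = ", "),
            if (sum(drop) > 8) ", ..." else "")
  table$values <- table$values[, !drop, drop = FALSE]
  table
}

#' Convert counts to relative abundances
#'
#' @param table a count [feature_table()] with positive sample totals.
#' @return A [feature_table()] whose rows each sum to 1
#'   (`value_kind = "concentration"`).
#' @export
relative_abundance <- function(table) {
  if (table$value_kind != "count") stop("relative_abundance expects a count table")
  totals <- rowSums(table$values)
  if (any(totals == 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(table$values)[totals == 0], collapse = ", "))
  feature_table(table$values / totals, layer = table$layer, value_kind = "concentration")
}

#' Principal component analysis of a normalized table
#'
#' Thin wrapper over [stats::prcomp()] used to summarize per-layer
#' variation after autoscaling.
#'
#' @param table an autoscaled [feature_table()].
#' @param n_components number of components to retain; must not exceed
#'   `min(n_samples - 1, n_features)`.
#' @return An object of class `pca_result`: list with `scores` (samples x
#'   components), `loadings` (features x components, column-orthonormal) and
#'   `explained_variance` (fractions, non-increasing, summing to <= 1).
#' @export
run_pca <- function(table, n_components = 2) {
  x <- table$values
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax)
    stop("n_components (", n_components, ") exceeds min(n_samples - 1, n_features) = ", kmax)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  keep <- seq_len(n_components)
  structure(list(scores = pr$x[, keep, drop = FALSE],
                 loadings = pr$rotation[, keep, drop = FALSE],
                 explained_variance = pr$sdev[keep]^2 / total_var),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", ncol(x$scores), "components; explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}
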