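#' Penalty and resampling configuration for stability selection
#'
#' @param alpha_en elastic-net mixing parameter for the EN arm (1 = pure
#'   LASSO; the LASSO arm always uses 1). Default 0.5.
#' @param n_lambda number of penalty grid points (default 50), log-spaced
#'   from the data-derived maximal penalty `lambda_max` (the smallest
#'   penalty with an empty L1 support) down to
#'   `lambda_min_ratio * lambda_max`. The grid is expressed as fractions of
#'   `lambda_max`, so the tuning range is scale-free.
#' @param lambda_min_ratio smallest grid fraction (default 0.001).
#' @param cv_folds cross-validation folds for penalty tuning (default 10),
#'   stratified by class; reduced with a warning when a class is smaller
#'   than the fold count.
#' @param train_fraction fraction of samples in each iteration's training
#'   split (default 0.75).
#' @param n_iterations number of resampling iterations (default 100).
#' @param resample `"subsample"` (default: independent stratified
#'   train-fraction re-splits) or `"bootstrap"` (stratified bootstrap
#'   resamples).
#' @param combine `"sum"` (default: combined frequency = LASSO + EN
#'   frequency) or `"union"` (per-iteration union of the two supports).
#' @param seed integer seed; per-iteration RNG substreams are derived from
#'   it.
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(alpha_en = 0.5, n_lambda = 50, lambda_min_ratio = 0.001,
                           cv_folds = 10, train_fraction = 0.75, n_iterations = 100,
                           resample = c("subsample", "bootstrap"),
                           combine = c("sum", "union"), seed = 1L) {
  stopifnot(alpha_en > 0, alpha_en <= 1, n_lambda >= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            cv_folds >= 2, train_fraction > 0, train_fraction < 1,
            n_iterations >= 1)
  structure(list(alpha_en = alpha_en, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, cv_folds = cv_folds,
                 train_fraction = train_fraction, n_iterations = n_iterations,
                 resample = match.arg(resample), combine = match.arg(combine),
                 seed = as.integer(seed)),
            class = "penalty_config")
}

as_binary_y <- function(y, positive = NULL) {
  f <- factor(y)
  if (nlevels(f) != 2) stop("y must contain exactly two classes")
  if (is.null(positive)) positive <- levels(f)[2]
  list(y01 = as.numeric(f == positive), positive = positive, levels = levels(f))
}

#' Maximal L1 penalty for penalized logistic regression
#'
#' The smallest penalty at which the L1 (or elastic-net) support is empty:
#' `max |x' (y - mean(y))| / (n * max(alpha, 1e-3))` with an unpenalized
#' intercept.
#'
#' @param x numeric matrix (autoscaled), samples in rows.
#' @param y binary labels.
#' @param alpha_mix elastic-net mixing (1 = LASSO).
#' @return The maximal penalty (a positive number).
#' @export
lambda_max <- function(x, y, alpha_mix = 1) {
  yb <- as_binary_y(y)$y01
  p0 <- mean(yb)
  max(abs(crossprod(x, yb - p0))) / (nrow(x) * max(alpha_mix, 1e-3))
}

lambda_grid_for <- function(x, y, alpha_mix, config) {
  lmax <- lambda_max(x, y, alpha_mix)
  lmax * exp(seq(0, log(config$lambda_min_ratio), length.out = config$n_lambda))
}

#' Fit a penalized logistic regression at one penalty
#'
#' Maximizes the binomial log-likelihood penalized by
#' `lambda * (alpha_mix * ||beta||_1 + (1 - alpha_mix)/2 * ||beta||_2^2)`
#' (objective scaled by 1/n, intercept unpenalized). Positive penalties are
#' solved by [glmnet::glmnet()] (coordinate descent, exact zeros where the
#' L1 subgradient condition holds); `lambda = 0` is fit by [stats::glm()].
#'
#' @param x numeric matrix (autoscaled), samples in rows; must be finite.
#' @param y binary labels (both classes present).
#' @param alpha_mix elastic-net mixing in `(0, 1]`; 1 = LASSO.
#' @param lambda nonnegative penalty.
#' @return List with `intercept`, `coefficients` (named vector, exact zeros
#'   preserved) and `lambda`.
#' @export
fit_penalized_logistic <- function(x, y, alpha_mix = 1, lambda) {
  if (any(!is.finite(x))) stop("x contains non-finite values")
  yb <- as_binary_y(y)
  if (lambda == 0) {
    fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, x), yb$y01,
                                           family = stats::binomial()))
    beta <- fit$coefficients[-1]
    names(beta) <- colnames(x)
    return(list(intercept = unname(fit$coefficients[1]), coefficients = beta,
                lambda = 0))
  }
  lmax <- lambda_max(x, yb$y01, alpha_mix)
  if (lambda >= lmax * (1 - 1e-12)) {
    # by definition of lambda_max the penalized optimum is the null model
    beta <- stats::setNames(rep(0, ncol(x)), colnames(x))
    return(list(intercept = stats::qlogis(mean(yb$y01)), coefficients = beta,
                lambda = lambda))
  }
  lseq <-
    unique(sort(c(exp(seq(log(lmax), log(lambda), length.out = 20)), lambda),
                decreasing = TRUE))
  fit <- quiet_glmnet(glmnet::glmnet(x, yb$y01, family = "binomial", alpha = alpha_mix,
                                     lambda = lseq, standardize = FALSE, thresh = 1e-10))
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta) <- colnames(x)
  list(intercept = fit$a0[[length(fit$a0)]], coefficients = beta, lambda = lambda)
}

# glmnet emits an advisory warning for class counts below 8; resampled
# training splits of a small matched cohort trip it constantly, so it is
# muffled at our call sites (other glmnet warnings propagate).
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

stratified_folds <- function(y01, k) {
  n_min <- min(table(y01))
  if (n_min < k) {
    warning("reducing cv_folds from ", k, " to ", n_min,
            " so every fold keeps both classes")
    k <- n_min
  }
  fold <- integer(length(y01))
  for (cl in unique(y01)) {
    idx <- which(y01 == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  list(fold = fold, k = k)
}

stratified_split <- function(y01, frac) {
  train <- integer(0)
  for (cl in unique(y01)) {
    idx <- which(y01 == cl)
    n_tr <- round(frac * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Choose the penalty by stratified cross-validated AUC
#'
#' Fits the full penalty path on each training fold and scores each grid
#' point by mean held-out AUC. The chosen penalty is the largest one whose
#' mean AUC is within one standard error of the best (the usual 1-SE
#' convention), which breaks ties — exact or within fold noise — toward
#' the sparser model; on pure-noise data this collapses to the null model
#' instead of chasing fold-level AUC fluctuations.
#'
#' @inheritParams fit_penalized_logistic
#' @param config a [penalty_config()] (grid length, min ratio, folds).
#' @param lambda_grid optional explicit descending penalty grid; default is
#'   derived from the data and `config`.
#' @return List with `lambda` (chosen), `lambda_grid` and `cv_auc` (mean
#'   held-out AUC per grid point).
#' @export
cv_optimize_lambda <- function(x, y, alpha_mix = 1, config = penalty_config(),
                               lambda_grid = NULL) {
  yb <- as_binary_y(y)
  if (is.null(lambda_grid)) lambda_grid <- lambda_grid_for(x, yb$y01, alpha_mix, config)
  if (any(diff(lambda_grid) >= 0)) stop("lambda grid must be strictly descending")
  if (length(lambda_grid) == 1)
    return(list(lambda = lambda_grid, lambda_grid = lambda_grid, cv_auc = NA_real_))
  fl <- stratified_folds(yb$y01, config$cv_folds)
  auc <- matrix(NA_real_, fl$k, length(lambda_grid))
  for (f in seq_len(fl$k)) {
    tr <- fl$fold != f
    fit <- quiet_glmnet(glmnet::glmnet(x[tr, , drop = FALSE], yb$y01[tr],
                                       family = "binomial", alpha = alpha_mix,
                                       lambda = lambda_grid, standardize = FALSE))
    sc <- stats::predict(fit, x[!tr, , drop = FALSE], s = lambda_grid)
    auc[f, ] <- apply(sc, 2L, compute_auc, labels = yb$y01[!tr], positive = 1)
  }
  mean_auc <- colMeans(auc)
  se <- apply(auc, 2L, stats::sd) / sqrt(fl$k)
  best <- which.max(mean_auc)  # first max = largest lambda on the descending grid
  chosen <- which(mean_auc >= mean_auc[best] - se[best])[1]
  list(lambda = lambda_grid[chosen], lambda_grid = lambda_grid, cv_auc = mean_auc,
       cv_se = se)
}

support_at <- function(fit, lambda) {
  beta <- stats::coef(fit, s = lambda, exact = FALSE)[-1, 1]
  which(beta != 0)
}

#' Stability selection with combined LASSO and elastic-net arms
#'
#' The core feature-selection procedure: over `n_iterations` stratified
#' resamples of the cohort, a LASSO (`alpha = 1`) and an elastic-net
#' (`alpha = alpha_en`) logistic model are tuned by stratified
#' cross-validated AUC and fit on the training part, and each feature's
#' selection (nonzero coefficient) is recorded. Features are ranked by the
#' combined selection frequency of the two arms; [select_first_quartile()]
#' then retains the top quartile of ever-selected features.
#'
#' @param x autoscaled numeric matrix (samples x features) or a normalized
#'   [feature_table()].
#' @param y two-level group labels.
#' @param config a [penalty_config()].
#' @return An object of class `stability_selection`: list with `freq`
#'   (data frame `feature_id, freq_lasso, freq_en, freq_combined, rank,
#'   selected`), `config`, `n_iterations` and `positive` (the modeled
#'   class).
#' @export
stability_selection <- function(x, y, config = penalty_config()) {
  if (inherits(x, "feature_table")) x <- x$values
  if (any(!is.finite(x))) stop("x contains non-finite values")
  yb <- as_binary_y(y)
  n <- nrow(x)
  stopifnot(length(yb$y01) == n)
  set.seed(config$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, config$n_iterations)
  alphas <- c(lasso = 1, en = config$alpha_en)
  freq <- matrix(0L, ncol(x), 2, dimnames = list(colnames(x), names(alphas)))
  for (it in seq_len(config$n_iterations)) {
    set.seed(iter_seeds[it])
    repeat {
      tr <- if (config$resample == "subsample") stratified_split(yb$y01, config$train_fraction)
            else {
              idx <- unlist(lapply(unique(yb$y01), function(cl) {
                i <- which(yb$y01 == cl); sample(i, length(i), replace = TRUE)
              }))
              sort(idx)
            }
      if (length(unique(yb$y01[tr])) == 2) break
      message("stability_selection: redrew a single-class training split (iteration ", it, ")")
    }
    xtr <- x[tr, , drop = FALSE]; ytr <- yb$y01[tr]
    sel <- list()
    for (m in names(alphas)) {
      cv <- suppressWarnings(cv_optimize_lambda(xtr, ytr, alphas[[m]], config))
      fit <- quiet_glmnet(glmnet::glmnet(xtr, ytr, family = "binomial",
                                         alpha = alphas[[m]],
                                         lambda = cv$lambda_grid, standardize = FALSE))
      sel[[m]] <- support_at(fit, cv$lambda)
    }
    if (config$combine == "union") {
      u <- union(sel$lasso, sel$en)
      freq[u, 1] <- freq[u, 1] + 1L
    } else {
      freq[sel$lasso, 1] <- freq[sel$lasso, 1] + 1L
      freq[sel$en, 2] <- freq[sel$en, 2] + 1L
    }
  }
  combined <- freq[, 1] + freq[, 2]
  df <- data.frame(feature_id = rownames(freq),
                   freq_lasso = freq[, 1], freq_en = freq[, 2],
                   freq_combined = combined,
                   rank = rank(-combined, ties.method = "min"),
                   stringsAsFactors = FALSE, row.names = NULL)
  obj <- structure(list(freq = df, config = config,
                        n_iterations = config$n_iterations,
                        positive = yb$positive),
                   class = "stability_selection")
  obj$freq$selected <- obj$freq$feature_id %in% select_first_quartile(obj)
  obj
}

#' First-quartile selection rule
#'
#' Among features that were selected at least once, retains those whose
#' combined frequency reaches the 75th percentile of the positive
#' frequencies (boundary ties included), in deterministic order (frequency
#' descending, then feature ID).
#'
#' @param selection a `stability_selection` object.
#' @return Character vector of selected feature IDs (empty, with a
#'   warning, if no feature was ever selected).
#' @export
select_first_quartile <- function(selection) {
  df <- selection$freq
  pos <- df$freq_combined > 0
  if (!any(pos)) {
    warning("no feature was ever selected")
    return(character(0))
  }
  thr <- stats::quantile(df$freq_combined[pos], 0.75, names = FALSE)
  keep <- df[pos & df$freq_combined >= thr, , drop = FALSE]
  keep <- keep[order(-keep$freq_combined, keep$feature_id), ]
  keep$feature_id
}

#' @export
print.stability_selection <- function(x, ...) {
  n_sel <- sum(x$freq$selected)
  cat(sprintf("<stability_selection> %d features, %d iterations x 2 arms; %d in first quartile\n",
              nrow(x$freq), x$n_iterations, n_sel))
  top <- x$freq[order(-x$freq$freq_combined), ][seq_len(min(5, nrow(x$freq))), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-16s combined %d/%d (LASSO %d, EN %d)%s\n", top$feature_id[i],
                top$freq_combined[i], 2L * x$n_iterations,
                top$freq_lasso[i], top$freq_en[i],
                if (top$selected[i]) " *" else ""))
  invisible(x)
}

#' @export
summary.stability_selection <- function(object, ...) {
  df <- object$freq[order(object$freq$rank), ]
  rownames(df) <- NULL
  df
}

#' Plot stability-selection frequencies
#'
#' Barplot of combined selection frequencies (descending) with the
#' first-quartile cutoff marked.
#'
#' @param x a `stability_selection` object.
#' @param n_top number of features to display.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.stability_selection <- function(x, n_top = 30, ...) {
  df <- x$freq[order(-x$freq$freq_combined), ]
  df <- df[seq_len(min(n_top, nrow(df))), ]
  pos <- x$freq$freq_combined[x$freq$freq_combined > 0]
  graphics::barplot(df$freq_combined, names.arg = df$feature_id, las = 2,
                    cex.names = 0.6, ylab = "combined selection frequency",
                    col = ifelse(df$selected, "steelblue", "grey70"), ...)
  if (length(pos))
    graphics::abline(h = stats::quantile(pos, 0.75), lty = 2)
  invisible(x)
}

#' Write a stability selection to TSV
#' @param selection a `stability_selection` object.
#' @param path output path.
#' @param layer optional layer tag column.
#' @return `path`, invisibly.
#' @export
write_stability <- function(selection, path, layer = NA_character_) {
  df <- summary(selection)
  df <- cbind(feature_id = df$feature_id, layer = layer,
              df[, c("freq_lasso", "freq_en", "freq_combined", "rank", "selected")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
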