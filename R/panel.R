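#' Fit a logistic panel model
#'
#' Unpenalized logistic maximum-likelihood fit of a small biomarker panel.
#' Under (quasi-)perfect separation the ML fit diverges; the fit is then
#' redone with a tiny ridge penalty (1e-6) and flagged.
#'
#' @param x numeric matrix restricted to the panel features (samples in
#'   rows) or a [feature_table()].
#' @param y two-level labels; the positive class is the second factor
#'   level unless `positive` is given.
#' @param positive optional positive-class label.
#' @return Object of class `panel_model`: list with `features`,
#'   `intercept`, `coefficients`, `separation` flag and `positive`.
#' @export
fit_panel <- function(x, y, positive = NULL) {
  if (inherits(x, "feature_table")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "feature"))
  if (ncol(x) == 0) stop("empty panel")
  yb <- as_binary_y(y, positive)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, x), yb$y01, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation || any(abs(fit$coefficients[-1]) > 1e3) || anyNA(fit$coefficients)) {
    separation <- TRUE
    xr <- if (ncol(x) >= 2) x else cbind(x, .dummy = 0)  # glmnet needs >= 2 columns
    # a descending path warm-starts the near-unpenalized ridge solution
    lpath <- c(10^(0:-4), 1e-6)
    rfit <- quiet_glmnet(glmnet::glmnet(xr, yb$y01, family = "binomial", alpha = 0,
                                        lambda = lpath, standardize = FALSE))
    co <- as.numeric(rfit$beta[, ncol(rfit$beta)])[seq_len(ncol(x))]
    names(co) <- colnames(x)
    out <- list(intercept = rfit$a0[[length(rfit$a0)]], coefficients = co)
  } else {
    co <- fit$coefficients[-1]
    names(co) <- colnames(x)
    out <- list(intercept = unname(fit$coefficients[1]), coefficients = co)
  }
  structure(list(features = colnames(x), intercept = out$intercept,
                 coefficients = out$coefficients, separation = separation,
                 positive = yb$positive),
            class = "panel_model")
}

#' @export
coef.panel_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.panel_model <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- newdata$values
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1)
  eta <- drop(newdata[, object$features, drop = FALSE] %*% object$coefficients) +
    object$intercept
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %d feature(s), positive class '%s'%s\n",
              length(x$features), x$positive,
              if (x$separation) " [ridge fallback: separation]" else ""))
  print(round(coef(x), 4))
  invisible(x)
}

#' Bootstrap AUC distribution of a panel
#'
#' Per iteration: stratified bootstrap resample, refit of the panel,
#' AUC evaluated on the out-of-bag samples (iterations whose out-of-bag
#' set misses a class are redrawn).
#'
#' @param x panel matrix (samples x panel features).
#' @param y two-level labels.
#' @param n_iterations number of bootstrap iterations (default 100).
#' @param seed integer seed.
#' @param positive optional positive-class label.
#' @return Numeric vector of out-of-bag AUCs, length `n_iterations`.
#' @export
bootstrap_auc <- function(x, y, n_iterations = 100, seed = 1L, positive = NULL) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "feature"))
  yb <- as_binary_y(y, positive)
  set.seed(seed)
  out <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    repeat {
      boot <- unlist(lapply(unique(yb$y01), function(cl) {
        idx <- which(yb$y01 == cl); sample(idx, length(idx), replace = TRUE)
      }))
      oob <- setdiff(seq_along(yb$y01), boot)
      if (length(unique(yb$y01[oob])) == 2) break
    }
    m <- fit_panel(x[boot, , drop = FALSE], yb$y01[boot], positive = 1)
    out[i] <- compute_auc(predict(m, x[oob, , drop = FALSE]), yb$y01[oob], positive = 1)
  }
  out
}

#' Permuted-label ("random") AUC null distribution
#'
#' Per iteration the labels are permuted, the panel is refit on a
#' stratified 75% training split of the permuted data, and the AUC is
#' evaluated on the held-out 25%. The mean of this distribution locates
#' chance performance for the panel and sample size at hand.
#'
#' @inheritParams bootstrap_auc
#' @param train_fraction training fraction for each permuted refit.
#' @return Numeric vector of held-out AUCs under permuted labels.
#' @export
permuted_auc_null <- function(x, y, n_iterations = 100, seed = 1L,
                              train_fraction = 0.75, positive = NULL) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "feature"))
  yb <- as_binary_y(y, positive)
  set.seed(seed)
  out <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    yp <- sample(yb$y01)
    tr <- stratified_split(yp, train_fraction)
    m <- fit_panel(x[tr, , drop = FALSE], yp[tr], positive = 1)
    out[i] <- compute_auc(predict(m, x[-tr, , drop = FALSE]), yp[-tr], positive = 1)
  }
  out
}

#' Sensitivity and specificity at the Youden-optimal threshold
#'
#' Scans all candidate thresholds and returns the one maximizing
#' sensitivity + specificity - 1 (Youden's J); ties are broken toward the
#' higher specificity. A sample is called positive when its score is at
#' least the threshold.
#'
#' @param scores numeric model scores.
#' @param labels two-level labels.
#' @param positive optional positive-class label.
#' @return List with `sensitivity`, `specificity` and `threshold`.
#' @export
sensitivity_specificity <- function(scores, labels, positive = NULL) {
  yb <- as_binary_y(labels, positive)
  pos <- yb$y01 == 1
  if (!any(pos) || all(pos)) stop("both classes must be present")
  cand <- c(sort(unique(scores)), Inf)
  sens <- vapply(cand, function(t) mean(scores[pos] >= t), 0)
  spec <- vapply(cand, function(t) mean(scores[!pos] < t), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  list(sensitivity = sens[best], specificity = spec[best], threshold = cand[best])
}

#' Evaluate a biomarker panel
#'
#' Full performance characterization of a fixed feature panel: logistic
#' fit on a stratified 75% training split with the point AUC computed on
#' the held-out 25% (`auc_test`), an apparent full-data AUC
#' (`auc_apparent`, labeled as such since resubstitution is optimistic),
#' bootstrap out-of-bag and permuted-label AUC distributions, and
#' sensitivity/specificity at the Youden threshold of the full-data
#' scores.
#'
#' @param x matrix or [feature_table()] (normalized) containing at least
#'   the panel features.
#' @param y two-level labels.
#' @param features character vector of panel feature IDs (default: all
#'   columns of `x`).
#' @param n_iterations iterations for both AUC distributions (default 100).
#' @param train_fraction training fraction for the point estimate.
#' @param seed integer seed.
#' @param positive optional positive-class label.
#' @return Object of class `panel_report`.
#' @export
evaluate_panel <- function(x, y, features = NULL, n_iterations = 100,
                           train_fraction = 0.75, seed = 1L, positive = NULL) {
  if (inherits(x, "feature_table")) x <- x$values
  if (is.null(features)) features <- colnames(x)
  missing_f <- setdiff(features, colnames(x))
  if (length(missing_f))
    stop("panel feature(s) absent from x: ", paste(missing_f, collapse = ", "))
  xp <- x[, features, drop = FALSE]
  yb <- as_binary_y(y, positive)
  set.seed(seed)
  tr <- stratified_split(yb$y01, train_fraction)
  m_tr <- fit_panel(xp[tr, , drop = FALSE], yb$y01[tr], positive = 1)
  auc_test <- compute_auc(predict(m_tr, xp[-tr, , drop = FALSE]), yb$y01[-tr], positive = 1)
  model <- fit_panel(xp, yb$y01, positive = 1)
  scores <- predict(model, xp)
  auc_apparent <- compute_auc(scores, yb$y01, positive = 1)
  boot <- bootstrap_auc(xp, yb$y01, n_iterations, seed = seed + 1L, positive = 1)
  null <- permuted_auc_null(xp, yb$y01, n_iterations, seed = seed + 2L,
                            train_fraction = train_fraction, positive = 1)
  ss <- sensitivity_specificity(scores, yb$y01, positive = 1)
  model$positive <- yb$positive
  structure(list(model = model, features = features,
                 auc_test = auc_test, auc_apparent = auc_apparent,
                 bootstrap_auc = boot, null_auc = null,
                 sensitivity = ss$sensitivity, specificity = ss$specificity,
                 threshold = ss$threshold,
                 training_samples = rownames(xp)[tr]),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("<panel_report> %d feature(s): %s\n", length(x$features),
              paste(utils::head(x$features, 6), collapse = ", ")))
  cat(sprintf("  AUC (held-out test)  %.3f\n", x$auc_test))
  cat(sprintf("  AUC (apparent)       %.3f\n", x$auc_apparent))
  cat(sprintf("  bootstrap AUC        mean %.3f [%.3f, %.3f]\n",
              mean(x$bootstrap_auc),
              stats::quantile(x$bootstrap_auc, 0.025),
              stats::quantile(x$bootstrap_auc, 0.975)))
  cat(sprintf("  permuted-label AUC   mean %.3f\n", mean(x$null_auc)))
  cat(sprintf("  sensitivity %.3f / specificity %.3f at threshold %.3g\n",
              x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' @export
coef.panel_report <- function(object, ...) coef(object$model)

#' Plot the AUC distributions of a panel report
#'
#' Overlaid histograms of the bootstrap ("true") and permuted-label
#' ("random") AUC distributions with the point estimate marked.
#'
#' @param x a `panel_report`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.panel_report <- function(x, ...) {
  br <- seq(0, 1, by = 0.025)
  h1 <- graphics::hist(x$null_auc, breaks = br, plot = FALSE)
  h2 <- graphics::hist(x$bootstrap_auc, breaks = br, plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  graphics::plot(h1, col = grDevices::adjustcolor("grey60", 0.6), ylim = ylim,
                 xlim = c(0, 1), main = "Panel AUC distributions", xlab = "AUC", ...)
  graphics::plot(h2, col = grDevices::adjustcolor("steelblue", 0.6), add = TRUE)
  graphics::abline(v = x$auc_test, lwd = 2)
  graphics::legend("topleft", fill = c("grey60", "steelblue"),
                   legend = c("permuted labels", "bootstrap"), bty = "n")
  invisible(x)
}

#' Serialize a panel report
#'
#' Writes the report summary as JSON and the two AUC distributions as a
#' TSV sidecar.
#'
#' @param report a `panel_report`.
#' @param path output JSON path; the sidecar gets suffix `_auc.tsv`.
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(report, path) {
  obj <- list(features = report$features,
              intercept = report$model$intercept,
              coefficients = as.list(report$model$coefficients),
              separation = report$model$separation,
              auc_test = report$auc_test,
              auc_apparent = report$auc_apparent,
              bootstrap = list(mean = mean(report$bootstrap_auc),
                               q025 = unname(stats::quantile(report$bootstrap_auc, 0.025)),
                               q975 = unname(stats::quantile(report$bootstrap_auc, 0.975))),
              null = list(mean = mean(report$null_auc),
                          q025 = unname(stats::quantile(report$null_auc, 0.025)),
                          q975 = unname(stats::quantile(report$null_auc, 0.975))),
              sensitivity = report$sensitivity,
              specificity = report$specificity,
              threshold = report$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  side <- sub("\\.json$", "", path)
  utils::write.table(data.frame(iteration = seq_along(report$bootstrap_auc),
                                bootstrap_auc = report$bootstrap_auc,
                                null_auc = report$null_auc),
                     paste0(side, "_auc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Hemoglobin-subunit reference panel evaluation
#'
#' Evaluates a fixed reference panel through the same fit/evaluate path as
#' any selected panel. The default reference IDs are the four hemoglobin
#' subunits used as a stand-in for the fecal immunochemical test; missing
#' IDs are skipped with a message.
#'
#' @param table a proteome [feature_table()] (normalized or raw; raw
#'   tables are autoscaled first).
#' @param y two-level labels.
#' @param reference_ids feature IDs of the reference panel.
#' @param ... passed to [evaluate_panel()].
#' @return A `panel_report` for the reference panel.
#' @export
reference_panel_auc <- function(table, y,
                                reference_ids = c("HBA1", "HBB", "HBD.HBE1", "HBG2.HBG1"),
                                ...) {
  if (inherits(table, "feature_table") && table$value_kind != "normalized")
    table <- autoscale(table)
  x <- if (inherits(table, "feature_table")) table$values else table
  present <- intersect(reference_ids, colnames(x))
  absent <- setdiff(reference_ids, colnames(x))
  if (length(absent))
    message("reference_panel_auc: skipping absent reference ID(s): ",
            paste(absent, collapse = ", "))
  if (!length(present)) stop("none of the reference IDs are present in the table")
  evaluate_panel(x, y, features = present, ...)
}
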