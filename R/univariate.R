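#' @importFrom stats optimise pchisq dbinom
NULL

# beta-binomial log-likelihood; phi is the intra-class correlation in [0, 1).
# phi below a small floor is evaluated as the binomial limit.
bb_loglik <- function(x, n, p, phi) {
  if (p <= 0 || p >= 1) return(-Inf)
  if (phi < 1e-8)
    return(sum(dbinom(x, n, p, log = TRUE)))
  a <- p * (1 - phi) / phi
  b <- (1 - p) * (1 - phi) / phi
  sum(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b))
}

# maximize a phi-profile log-likelihood over [0, 0.999]. The profile can be
# multimodal (boundary binomial mode vs an interior overdispersed mode), so a
# log-spaced grid scan brackets the best region before local refinement;
# plain golden-section over the whole interval can miss the global maximum.
bb_maximise_phi <- function(profile_ll) {
  grid <- c(0, exp(seq(log(1e-5), log(0.999), length.out = 30)))
  vals <- vapply(grid, profile_ll, 0)
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  if (lo == hi) return(vals[i])
  opt <- optimise(profile_ll, lower = lo, upper = hi, maximum = TRUE, tol = 1e-8)
  max(opt$objective, vals[i])
}

# profile ML over the proportion(s) at fixed phi. At phi = 0 the pooled
# (or per-group) empirical proportion is the exact MLE; otherwise a bounded
# 1-d optimise is used.
bb_profile_p <- function(x, n, phi) {
  phat <- sum(x) / sum(n)
  if (phi < 1e-8) return(bb_loglik(x, n, min(max(phat, 1e-12), 1 - 1e-12), 0))
  if (sum(x) == 0) phat <- 0.5 / sum(n)
  if (sum(x) == sum(n)) phat <- 1 - 0.5 / sum(n)
  opt <- optimise(function(p) bb_loglik(x, n, p, phi),
                  lower = 1e-9, upper = 1 - 1e-9, maximum = TRUE, tol = 1e-9)
  opt$objective
}

#' Beta-binomial likelihood-ratio test for two groups of count proportions
#'
#' Tests whether the underlying proportion of a count (e.g. a protein's
#' spectral counts out of per-sample totals) differs between two groups,
#' allowing overdispersion relative to the binomial. The null model fits a
#' common proportion and a common overdispersion; the alternative fits
#' group-specific proportions with a shared overdispersion. The
#' overdispersion (beta-binomial intra-class correlation) is estimated by
#' bounded profile maximization over `[0, 0.999]`, with the boundary value
#' 0 reducing the model to the binomial. The statistic is twice the
#' log-likelihood-ratio, referred to chi-square with 1 df.
#'
#' @param counts_a,counts_b per-sample counts in each group.
#' @param totals_a,totals_b per-sample totals (counts <= totals, totals > 0).
#' @param overdispersion `NULL` to estimate by ML, or a fixed value
#'   (0 gives the plain binomial likelihood-ratio test).
#' @return List of class `differential_result` with `statistic`, `p_value`,
#'   and `degenerate` (TRUE when all counts are zero in both groups, in
#'   which case `p_value = 1`).
#' @export
beta_binomial_test <- function(counts_a, totals_a, counts_b, totals_b,
                               overdispersion = NULL) {
  stopifnot(length(counts_a) == length(totals_a),
            length(counts_b) == length(totals_b),
            length(counts_a) >= 2, length(counts_b) >= 2)
  if (any(counts_a > totals_a) || any(counts_b > totals_b))
    stop("counts must not exceed totals")
  if (any(totals_a <= 0) || any(totals_b <= 0)) stop("totals must be positive")
  if (sum(counts_a) + sum(counts_b) == 0)
    return(structure(list(statistic = 0, p_value = 1, degenerate = TRUE),
                     class = "differential_result"))
  x <- c(counts_a, counts_b); n <- c(totals_a, totals_b)
  ll_null <- function(phi) bb_profile_p(x, n, phi)
  ll_alt <- function(phi) bb_profile_p(counts_a, totals_a, phi) +
    bb_profile_p(counts_b, totals_b, phi)
  if (is.null(overdispersion)) {
    l0 <- bb_maximise_phi(ll_null)
    l1 <- bb_maximise_phi(ll_alt)
  } else {
    stopifnot(overdispersion >= 0, overdispersion < 1)
    l0 <- ll_null(overdispersion)
    l1 <- ll_alt(overdispersion)
  }
  stat <- max(0, 2 * (l1 - l0))
  structure(list(statistic = stat,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("statistic = %.4g, p = %.4g%s\n", x$statistic, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate: all counts zero)" else ""))
  invisible(x)
}

#' Fold change between two groups
#'
#' `(mean(values_a) + pseudocount) / (mean(values_b) + pseudocount)`, with a
#' significance flag when the ratio is beyond the threshold in either
#' direction (>= threshold or <= 1/threshold).
#'
#' @param values_a,values_b nonnegative values per group.
#' @param pseudocount added to both group means (default 1, appropriate for
#'   spectral counts; use 0 for concentrations).
#' @param threshold flag threshold (default 2).
#' @return List with `fold_change` and `significant_fc`.
#' @export
fold_change <- function(values_a, values_b, pseudocount = 1, threshold = 2) {
  stopifnot(all(values_a >= 0), all(values_b >= 0))
  fc <- (mean(values_a) + pseudocount) / (mean(values_b) + pseudocount)
  list(fold_change = fc, significant_fc = fc >= threshold | fc <= 1 / threshold)
}

#' Welch two-sample t-test
#'
#' Wrapper over [stats::t.test()] (unequal variances, Welch-Satterthwaite
#' df) returning the statistic and two-sided p-value. The degenerate case
#' of zero variance in both groups with equal means yields `t = 0, p = 1`.
#'
#' @param values_a,values_b numeric vectors (>= 2 each).
#' @return List with `statistic` and `p_value`.
#' @export
welch_t_test <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  res <- tryCatch(stats::t.test(values_a, values_b, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b))))
      return(list(statistic = 0, p_value = 1))
    stop("t-test failed on degenerate input with unequal means")
  }
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' AUC of a single score vector (Mann-Whitney)
#'
#' Computes the area under the ROC curve of `values` as a score for the
#' positive class, via the rank (Mann-Whitney) formulation with half credit
#' for ties. For single-feature screening the orientation is normalized so
#' the reported AUC is >= 0.5, with the applied orientation recorded; model
#' scores should be evaluated unflipped via [compute_auc()].
#'
#' @param values numeric scores.
#' @param labels two-level vector; the positive class is the second level
#'   of `factor(labels)` unless `positive` is given.
#' @param positive optional positive-class label.
#' @param orient if `TRUE` (default), flip so AUC >= 0.5.
#' @return List with `auc` and `flipped`; for `compute_auc` the bare number.
#' @export
feature_auc <- function(values, labels, positive = NULL, orient = TRUE) {
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(f)[2]
  pos <- f == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)  # average ranks give half credit to ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  flipped <- FALSE
  if (orient && auc < 0.5) {
    auc <- 1 - auc
    flipped <- TRUE
  }
  list(auc = auc, flipped = flipped)
}

#' @rdname feature_auc
#' @param scores model scores (higher = more case-like).
#' @return `compute_auc` returns the AUC as a bare number, without
#'   orientation normalization (a chance-level model scores ~0.5 and a
#'   worse-than-chance model scores below 0.5, as required for honest
#'   permutation nulls).
#' @export
compute_auc <- function(scores, labels, positive = NULL) {
  feature_auc(scores, labels, positive = positive, orient = FALSE)$auc
}

#' Shannon alpha diversity of one sample (nats)
#'
#' `-sum(p_i log p_i)` over the nonzero proportions of a count vector,
#' computed via [vegan::diversity()].
#'
#' @param count_row nonnegative counts with positive total.
#' @return Shannon entropy in nats.
#' @export
shannon_alpha <- function(count_row) {
  if (sum(count_row) <= 0) stop("sample has zero total count")
  unname(vegan::diversity(count_row, index = "shannon"))
}

#' Bray-Curtis PERMANOVA between groups
#'
#' Computes Bray-Curtis dissimilarities on relative abundances and a
#' permutational MANOVA (pseudo-F on between/within sums of squared
#' distances) via [vegan::adonis2()], with `(count >= observed + 1) /
#' (n_perm + 1)` permutation p-value.
#'
#' @param table a count [feature_table()].
#' @param labels group labels (>= 3 samples per group).
#' @param n_perm number of permutations (default 999; < 99 warns).
#' @return List of class `diversity_result` with `alpha` (per-sample
#'   Shannon, nats), `distance` (Bray-Curtis `dist`), `pseudo_f` and
#'   `p_value`.
#' @export
bray_curtis_permanova <- function(table, labels, n_perm = 999) {
  if (n_perm < 99) warning("fewer than 99 permutations gives a coarse p-value")
  tab <- table(labels)
  if (any(tab < 3)) stop("need at least 3 samples per group")
  rel <- relative_abundance(table)
  d <- vegan::vegdist(rel$values, method = "bray")
  grp <- data.frame(group = factor(labels))
  fit <- vegan::adonis2(d ~ group, data = grp, permutations = n_perm)
  structure(list(alpha = apply(table$values, 1, shannon_alpha),
                 distance = d,
                 pseudo_f = fit$F[1],
                 p_value = fit$`Pr(>F)`[1]),
            class = "diversity_result")
}

#' Per-feature differential table for one comparison
#'
#' Runs the beta-binomial test (count layers) or Welch t-test
#' (concentrations) plus fold change for every feature of a table.
#'
#' @param table a [feature_table()].
#' @param labels two-level group vector aligned with the table's samples;
#'   fold change and the test contrast the first level vs the second.
#' @param test `"beta_binomial"` or `"welch"`; default chosen by
#'   `value_kind`.
#' @param pseudocount for [fold_change()]; default 1 for counts, 0
#'   otherwise.
#' @param fc_threshold fold-change flag threshold.
#' @param adjust if TRUE, add Benjamini-Hochberg adjusted p-values.
#' @return data frame `feature_id, statistic, p_value, fold_change,
#'   significant` (+ `adjusted_p`).
#' @export
differential_table <- function(table, labels, test = NULL, pseudocount = NULL,
                               fc_threshold = 2, adjust = FALSE) {
  f <- factor(labels)
  stopifnot(nlevels(f) == 2)
  if (is.null(test))
    test <- if (table$value_kind == "count") "beta_binomial" else "welch"
  if (is.null(pseudocount))
    pseudocount <- if (table$value_kind == "count") 1 else 0
  a <- f == levels(f)[1]
  x <- table$values
  totals <- rowSums(x)
  out <- lapply(seq_len(ncol(x)), function(j) {
    va <- x[a, j]; vb <- x[!a, j]
    if (test == "beta_binomial") {
      r <- beta_binomial_test(va, totals[a], vb, totals[!a])
    } else {
      r <- welch_t_test(va, vb)
    }
    fc <- fold_change(va, vb, pseudocount = pseudocount, threshold = fc_threshold)
    data.frame(feature_id = colnames(x)[j], statistic = r$statistic,
               p_value = r$p_value, fold_change = fc$fold_change,
               significant = r$p_value < 0.05 & fc$significant_fc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (adjust) out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
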