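test_that("penalties at or above lambda_max empty the support; lambda=0 is the ML fit", {
  set.seed(31)
  x <- rand_matrix(80, 5, seed = 31)
  y01 <- rbinom(80, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 2]))
  lmax <- lambda_max(x, y01, alpha_mix = 1)
  for (lam in c(lmax, 1.5 * lmax)) {
    fit <- fit_penalized_logistic(x, y01, alpha_mix = 1, lambda = lam)
    expect_true(all(fit$coefficients == 0))
  }
  fit_en <- fit_penalized_logistic(x, y01, alpha_mix = 0.5,
                                   lambda = lambda_max(x, y01, 0.5))
  expect_true(all(fit_en$coefficients == 0))

  x3 <- rand_matrix(200, 3, seed = 32)
  y3 <- rbinom(200, 1, plogis(1.2 * x3[, 1] - 0.7 * x3[, 3]))
  fit0 <- fit_penalized_logistic(x3, y3, alpha_mix = 1, lambda = 0)
  oracle <- logistic_ml_oracle(x3, y3)
  expect_equal(unname(c(fit0$intercept, fit0$coefficients)), oracle,
               tolerance = 1e-4)
  expect_error(fit_penalized_logistic(cbind(x3, NA), y3, 1, 0.1), "non-finite")
})

test_that("penalized solutions beat a brute-force grid on the objective", {
  set.seed(33)
  x <- rand_matrix(60, 2, seed = 33)
  y01 <- rbinom(60, 1, plogis(x[, 1]))
  for (alpha in c(1, 0.5)) {
    lam <- 0.3 * lambda_max(x, y01, alpha)
    fit <- fit_penalized_logistic(x, y01, alpha_mix = alpha, lambda = lam)
    f_star <- penalized_objective(fit$intercept, fit$coefficients, x, y01, alpha, lam)
    grid <- seq(-0.6, 0.6, length.out = 201)
    best_grid <- Inf
    for (b1 in grid) {
      vals <- vapply(grid, function(b2)
        penalized_objective(fit$intercept, c(fit$coefficients[1] + b1,
                                             fit$coefficients[2] + b2),
                            x, y01, alpha, lam), 0)
      best_grid <- min(best_grid, min(vals))
    }
    expect_lte(f_star, best_grid + 1e-8)
  }
})

test_that("cross-validated penalty choice reacts to signal and is degenerate-safe", {
  cfg <- penalty_config(cv_folds = 5, n_lambda = 30, seed = 1)
  # single-point grid returns it
  x <- rand_matrix(40, 4, seed = 35)
  y01 <- rep(c(0, 1), 20)
  expect_equal(cv_optimize_lambda(x, y01, 1, cfg, lambda_grid = 0.2)$lambda, 0.2)

  # pure noise: the 1-SE tie-break keeps chosen models sparse (typically a
  # handful of the 30 features, often none), never routinely dense
  sizes <- integer(20)
  for (s in 1:20) {
    xs <- rand_matrix(40, 30, seed = 400 + s)
    ys <- rep(c(0, 1), 20)
    set.seed(500 + s)
    cv <- suppressWarnings(cv_optimize_lambda(xs, ys, 1, cfg))
    fit <- fit_penalized_logistic(xs, ys, 1, cv$lambda)
    sizes[s] <- sum(fit$coefficients != 0)
  }
  expect_lte(median(sizes), 5)
  expect_gte(sum(sizes <= 10), 16)

  # one strong feature: kept at the chosen penalty
  kept <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    xs <- rand_matrix(60, 20, seed = 600 + s)
    ys <- rbinom(60, 1, plogis(2 * xs[, 7]))
    if (length(unique(ys)) < 2) next
    cv <- suppressWarnings(cv_optimize_lambda(xs, ys, 1, cfg))
    fit <- fit_penalized_logistic(xs, ys, 1, cv$lambda)
    kept <- kept + (fit$coefficients[7] != 0)
  }
  expect_gte(kept, 18)
})

test_that("L1 support size is near-monotone along the penalty path", {
  set.seed(37)
  x <- rand_matrix(50, 20, seed = 37)
  y01 <- rbinom(50, 1, plogis(x[, 1] - x[, 2]))
  lmax <- lambda_max(x, y01, 1)
  grid <- lmax * exp(seq(0, log(0.001), length.out = 50))
  sizes <- vapply(grid, function(l)
    sum(fit_penalized_logistic(x, y01, 1, l)$coefficients != 0), 0L)
  growing <- mean(diff(sizes) >= 0)  # sizes grow as lambda shrinks
  expect_gte(growing, 0.95)
})

test_that("stability selection is deterministic and recovers a planted feature", {
  bench <- benchmark_data(seed = 41, n_per_group = 30, p = 60, n_planted = 1,
                          effect = 2)
  cfg <- penalty_config(n_iterations = 20, cv_folds = 5, n_lambda = 30, seed = 9)
  s1 <- stability_selection(bench$x, bench$y, cfg)
  s2 <- stability_selection(bench$x, bench$y, cfg)
  expect_identical(s1$freq, s2$freq)
  top <- s1$freq$feature_id[which.min(s1$freq$rank)]
  expect_identical(top, "F001")
  expect_gte(s1$freq$freq_combined[s1$freq$feature_id == "F001"], 28)
  expect_true("F001" %in% select_first_quartile(s1))
})

test_that("label permutation collapses planted-feature frequencies to noise level", {
  bench <- benchmark_data(seed = 43, n_per_group = 30, p = 60, n_planted = 2,
                          effect = 2)
  cfg <- penalty_config(n_iterations = 20, cv_folds = 5, n_lambda = 30, seed = 5)
  real <- stability_selection(bench$x, bench$y, cfg)
  f_real <- real$freq$freq_combined[match(bench$planted, real$freq$feature_id)]
  set.seed(77)
  yperm <- sample(bench$y)
  perm <- stability_selection(bench$x, yperm, cfg)
  noise <- perm$freq$freq_combined[!perm$freq$feature_id %in% bench$planted]
  f_perm <- perm$freq$freq_combined[match(bench$planted, perm$freq$feature_id)]
  expect_true(all(f_real >= 30))
  expect_true(all(f_perm <= mean(noise) + 2 * sd(noise) + 1))
})

test_that("noise-only runs keep selection frequencies low for nearly all features", {
  # on a fixed noise cohort the single most y-correlated feature can be
  # selected often (subsampling preserves in-sample correlation), but the
  # bulk of features must stay rarely selected or first-quartile retention
  # would be meaningless
  cfg <- penalty_config(n_iterations = 25, cv_folds = 5, n_lambda = 30, seed = 2)
  max_possible <- 2 * cfg$n_iterations
  for (s in 1:5) {
    x <- rand_matrix(40, 50, seed = 700 + s)
    y <- rep(c("a", "b"), 20)
    sel <- stability_selection(x, y, cfg)
    f <- sel$freq$freq_combined
    expect_lte(mean(f), 0.25 * max_possible)
    expect_lte(mean(f >= 0.5 * max_possible), 0.10)
  }
})

test_that("first-quartile rule keeps the top 25% of ever-selected features inclusively", {
  fake <- function(freqs, n_iter = 100) {
    df <- data.frame(feature_id = sprintf("F%02d", seq_along(freqs)),
                     freq_lasso = pmin(freqs, n_iter),
                     freq_en = pmax(freqs - n_iter, 0),
                     freq_combined = freqs,
                     rank = rank(-freqs, ties.method = "min"),
                     stringsAsFactors = FALSE)
    structure(list(freq = df, n_iterations = n_iter), class = "stability_selection")
  }
  expect_identical(select_first_quartile(fake(c(200, 150, 10, 2, 0))), "F01")
  expect_identical(select_first_quartile(fake(rep(40, 6))),
                   sprintf("F%02d", 1:6))
  expect_warning(out <- select_first_quartile(fake(rep(0, 4))), "ever selected")
  expect_identical(out, character(0))
  # boundary ties are all included
  expect_identical(select_first_quartile(fake(c(100, 100, 100, 100, 1, 1, 1, 1))),
                   sprintf("F%02d", 1:4))
})

test_that("penalty_config validates its invariants", {
  expect_error(penalty_config(train_fraction = 1), "train_fraction")
  expect_error(penalty_config(cv_folds = 1), "cv_folds")
  expect_error(penalty_config(lambda_min_ratio = 2), "lambda_min_ratio")
  expect_error(cv_optimize_lambda(rand_matrix(10, 2), rep(0:1, 5), 1,
                                  lambda_grid = c(0.1, 0.2)),
               "descending")
})
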