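test_that("panel fits carry the right sign and match the ML oracle", {
  set.seed(51)
  x1 <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "biomarker"))
  y <- rbinom(60, 1, plogis(1.5 * x1[, 1]))
  m <- fit_panel(x1, y, positive = 1)
  expect_gt(m$coefficients["biomarker"], 0)

  x2 <- rand_matrix(100, 2, seed = 52)
  y2 <- rbinom(100, 1, plogis(0.8 * x2[, 1] - 0.4 * x2[, 2]))
  m2 <- fit_panel(x2, y2, positive = 1)
  oracle <- logistic_ml_oracle(x2, y2)
  expect_equal(unname(coef(m2)), oracle, tolerance = 1e-4)
  expect_false(m2$separation)
  expect_error(fit_panel(x2[, 0, drop = FALSE], y2), "empty panel")
})

test_that("perfect separation falls back to a flagged finite ridge fit", {
  x <- matrix(c(1:5, 11:15), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c("ctrl", "case"), each = 5)
  m <- fit_panel(x, y, positive = "case")
  expect_true(m$separation)
  expect_true(all(is.finite(coef(m))))
  expect_gt(m$coefficients["f"], 0)
})

test_that("compute_auc shares the pair-count contract without orientation flips", {
  set.seed(53)
  v <- rnorm(40)
  lab <- rep(c("case", "ctrl"), 20)
  expect_equal(compute_auc(v, lab, positive = "case"),
               auc_pair_oracle(v, lab, "case"), tolerance = 1e-12)
  # a worse-than-chance score stays below 0.5
  expect_equal(compute_auc(v, lab, positive = "case") +
                 compute_auc(-v, lab, positive = "case"), 1, tolerance = 1e-12)
})

test_that("bootstrap AUC is 1 for separable data, deterministic, and centered for noise", {
  x <- matrix(c(rnorm(20, -4), rnorm(20, 4)), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), each = 20)
  b <- bootstrap_auc(x, y, n_iterations = 20, seed = 3, positive = 1)
  expect_true(all(b == 1))
  expect_identical(b, bootstrap_auc(x, y, n_iterations = 20, seed = 3, positive = 1))
  expect_error(bootstrap_auc(x, y, n_iterations = 0), "n_iterations")

  set.seed(54)
  xn <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  yn <- rep(c(0, 1), 30)
  bn <- bootstrap_auc(xn, yn, n_iterations = 100, seed = 4, positive = 1)
  expect_gt(mean(bn), 0.40)
  expect_lt(mean(bn), 0.60)
})

test_that("bootstrap AUC spread shrinks with sample size", {
  sd_small <- sd_large <- numeric(5)
  for (s in 1:5) {
    set.seed(800 + s)
    mk <- function(n) {
      x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
      y <- rbinom(n, 1, plogis(1.2 * x[, 1]))
      if (length(unique(y)) < 2) y[1:2] <- 0:1
      list(x = x, y = y)
    }
    d1 <- mk(50); d2 <- mk(200)
    sd_small[s] <- sd(bootstrap_auc(d1$x, d1$y, 60, seed = s, positive = 1))
    sd_large[s] <- sd(bootstrap_auc(d2$x, d2$y, 60, seed = s, positive = 1))
  }
  expect_lt(mean(sd_large), mean(sd_small))
})

test_that("permuted-label nulls are centered and rank signal monotonically", {
  set.seed(55)
  x <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), 40)
  effects <- c(0, 2)
  percentiles <- vapply(effects, function(e) {
    xe <- x
    xe[y == 1, 1] <- xe[y == 1, 1] + e
    null <- permuted_auc_null(xe, y, n_iterations = 60, seed = 6, positive = 1)
    obs <- evaluate_panel(xe, y, n_iterations = 5, seed = 7, positive = 1)$auc_apparent
    mean(null < obs)
  }, 0)
  expect_gt(percentiles[2], percentiles[1])
  null0 <- permuted_auc_null(x, y, n_iterations = 100, seed = 8, positive = 1)
  expect_gt(mean(null0), 0.43)
  expect_lt(mean(null0), 0.57)
  expect_error(permuted_auc_null(x, y, n_iterations = 0), "n_iterations")
})

test_that("Youden threshold matches an exhaustive scan and handles degenerate scores", {
  perf <- sensitivity_specificity(c(1, 2, 3, 7, 8, 9),
                                  rep(c("ctrl", "case"), each = 3),
                                  positive = "case")
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)

  flat <- sensitivity_specificity(rep(2, 10), rep(c("case", "ctrl"), 5),
                                  positive = "case")
  expect_equal(flat$sensitivity + flat$specificity, 1)

  set.seed(56)
  sc <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)
  lab <- sample(rep(c("case", "ctrl"), 25))
  got <- sensitivity_specificity(sc, lab, positive = "case")
  pos <- lab == "case"
  best_oracle <- -Inf
  for (t in c(sort(unique(sc)), Inf)) {
    j <- mean(sc[pos] >= t) + mean(sc[!pos] < t) - 1
    best_oracle <- max(best_oracle, j)
  }
  expect_equal(got$sensitivity + got$specificity - 1, best_oracle,
               tolerance = 1e-12)
})

test_that("a fitted panel is not dominated by its own members on training data", {
  set.seed(57)
  x <- rand_matrix(60, 3, seed = 57)
  y <- rbinom(60, 1, plogis(x[, 1] + 0.5 * x[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  m <- fit_panel(x, y, positive = 1)
  panel_auc <- compute_auc(predict(m, x), y, positive = 1)
  for (j in 1:3) {
    single <- feature_auc(x[, j], y, positive = 1)$auc
    expect_gte(panel_auc, single - 0.02)
  }
})

test_that("panel reports assemble, print and serialize coherently", {
  bench <- benchmark_data(seed = 58, n_per_group = 20, p = 6, n_planted = 2,
                          effect = 1.5)
  rep1 <- evaluate_panel(bench$x, bench$y, features = c("F001", "F002"),
                         n_iterations = 30, seed = 9, positive = "case")
  expect_s3_class(rep1, "panel_report")
  expect_true(all(c(rep1$bootstrap_auc, rep1$null_auc) >= 0))
  expect_true(all(c(rep1$bootstrap_auc, rep1$null_auc) <= 1))
  expect_true(rep1$sensitivity >= 0 && rep1$sensitivity <= 1)
  expect_output(print(rep1), "bootstrap AUC")
  path <- file.path(withr::local_tempdir(), "panel.json")
  write_panel_report(rep1, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$features), rep1$features)
  expect_equal(back$auc_test, rep1$auc_test, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.json$", "_auc.tsv", path)))
  expect_error(evaluate_panel(bench$x, bench$y, features = "F999"), "absent")
})

test_that("the hemoglobin reference panel runs through the shared evaluation path", {
  bench <- benchmark_data(seed = 59, n_per_group = 20, p = 8, n_planted = 2,
                          effect = 1.5)
  x <- bench$x
  colnames(x)[1:4] <- c("HBA1", "HBB", "HBD.HBE1", "HBG2.HBG1")
  tb <- feature_table(unclass(x), "proteome", "normalized")
  ref <- reference_panel_auc(tb, bench$y, n_iterations = 20, seed = 11,
                             positive = "case")
  same <- evaluate_panel(x, bench$y, features = c("HBA1", "HBB", "HBD.HBE1", "HBG2.HBG1"),
                         n_iterations = 20, seed = 11, positive = "case")
  expect_equal(ref$auc_test, same$auc_test)
  expect_equal(coef(ref), coef(same))

  expect_message(partial <- reference_panel_auc(tb, bench$y,
                                                reference_ids = c("HBA1", "NOPE"),
                                                n_iterations = 5, seed = 2,
                                                positive = "case"),
                 "NOPE")
  expect_identical(partial$features, "HBA1")
  expect_error(reference_panel_auc(tb, bench$y, reference_ids = "NOPE"),
               "none of the reference IDs")
})
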