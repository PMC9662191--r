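small_meta <- function(n, groups = c("CRC", "control"), seed = 1) {
  set.seed(seed)
  cohort_metadata(sprintf("S%03d", seq_len(n)),
                  rep(groups, length.out = n))
}

test_that("default design reproduces the emulated cohort shapes bit-identically", {
  d <- cohort_design(seed = 7)
  co <- generate_cohort(d)
  expect_equal(dim(co$tables$microbiota$values), c(53, 225))
  expect_equal(dim(co$tables$proteome$values), c(53, 521))
  expect_equal(dim(co$tables$amino_acid$values), c(53, 44))
  expect_identical(sample_ids(co$tables$microbiota),
                   sample_ids(co$tables$proteome))
  expect_identical(co$meta$sample_id, sample_ids(co$tables$amino_acid))
  expect_identical(co, generate_cohort(d))
  # count layers are nonnegative integers; concentrations nonnegative
  expect_true(all(co$tables$microbiota$values >= 0))
  expect_true(all(co$tables$proteome$values == round(co$tables$proteome$values)))
  expect_true(all(co$tables$amino_acid$values >= 0))
})

test_that("invalid designs are rejected naming the offending entry", {
  expect_error(cohort_design(planted = list(
    planted_signal("metabolome", 1, c("CRC", "control"), 1))),
    "metabolome")
  expect_error(cohort_design(planted = list(
    planted_signal("amino_acid", 99, c("CRC", "control"), 1))),
    "99")
  expect_error(cohort_design(latent_factors = list(
    latent_factor(data.frame(layer_name = "lipidome", feature_index = 1,
                             loading = 0.5)))),
    "lipidome")
  expect_error(cohort_design(group_sizes = c(CRC = 1, control = 20)),
               "at least 2")
  expect_error(layer_spec("amino_acid", 5, sdlog = -1), "variance")
})

test_that("Dirichlet-multinomial with zero overdispersion reduces to the binomial", {
  spec <- layer_spec("microbiota", 2, depth_location = 100,
                     depth_dispersion = 0, overdispersion = 0,
                     baseline_profile = c(0.5, 0.5))
  meta <- small_meta(1000)
  tb <- sample_microbiome_layer(spec, meta, seed = 11)
  expect_true(all(rowSums(tb$values) == 100))
  # binomial(100, 0.5) oracle by direct sampling
  set.seed(12)
  oracle <- rbinom(1000, 100, 0.5)
  se <- sqrt(100 * 0.25 / 1000)
  expect_lt(abs(mean(tb$values[, 1]) - 50), 3 * se)
  expect_lt(abs(mean(oracle) - mean(tb$values[, 1])), 4 * se)
})

test_that("microbiome depth and null group exchangeability match the design", {
  spec <- layer_spec("microbiota", 20, overdispersion = 0.02)
  meta <- small_meta(500)
  tb <- sample_microbiome_layer(spec, meta, seed = 21)
  med <- median(rowSums(tb$values))
  expect_lt(abs(med - 23041) / 23041, 0.10)
  # no planted effect: group mean relative abundances differ < 3 SE
  rel <- relative_abundance(tb)$values
  a <- meta$group == "CRC"
  for (j in c(1, 10, 20)) {
    diff_se <- sqrt(var(rel[a, j]) / sum(a) + var(rel[!a, j]) / sum(!a))
    expect_lt(abs(mean(rel[a, j]) - mean(rel[!a, j])), 3 * diff_se)
  }
})

test_that("proteome counts have binomial means and planted proportion ratios", {
  spec <- layer_spec("proteome", 2, depth_location = 500, depth_dispersion = 0,
                     overdispersion = 0, baseline_profile = c(0.05, 0.02))
  meta <- small_meta(2000)
  tb <- sample_proteome_layer(spec, meta, seed = 31)
  se <- sqrt(500 * 0.05 * 0.95 / 2000)
  expect_lt(abs(mean(tb$values[, 1]) - 500 * 0.05), 3 * se)

  # planted log-fold log(2) on the case group: ratio of group mean underlying
  # proportions (counts over the fixed sample total) lands in [1.8, 2.2]
  spec2 <- layer_spec("proteome", 3, depth_location = 800, depth_dispersion = 0,
                      overdispersion = 0.01,
                      baseline_profile = c(0.04, 0.02, 0.01))
  meta2 <- small_meta(400)
  tb2 <- sample_proteome_layer(spec2, meta2,
                               planted = list(planted_signal("proteome", 1,
                                                             c("CRC", "control"), log(2))),
                               seed = 32)
  a <- meta2$group == "CRC"
  ratio <- mean(tb2$values[a, 1] / 800) / mean(tb2$values[!a, 1] / 800)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("per-sample detection counts sit at the emulated medians", {
  d <- cohort_design(seed = 17)
  co <- generate_cohort(d)
  det_prot <- median(rowSums(co$tables$proteome$values > 0))
  expect_gt(det_prot, 140)
  expect_lt(det_prot, 200)
  det_aa <- median(rowSums(co$tables$amino_acid$values > 0))
  expect_gt(det_aa, 22)
  expect_lt(det_aa, 30)
})

test_that("amino-acid planted shifts land on the log scale as specified", {
  spec <- layer_spec("amino_acid", 4, sdlog = 0.5,
                     baseline_profile = rep(log(50), 4), detect_prob = 1)
  meta <- small_meta(400)
  effect <- 1.2  # standardized; applied shift = effect * sdlog
  tb <- sample_amino_acid_layer(spec, meta,
                                planted = list(planted_signal("amino_acid", 2,
                                                              c("CRC", "control"), effect)),
                                seed = 41)
  a <- meta$group == "CRC"
  lg <- log(tb$values)
  for (j in c(1, 3)) {  # null features: log-means equal within 3 SE
    se <- sqrt(var(lg[a, j]) / sum(a) + var(lg[!a, j]) / sum(!a))
    expect_lt(abs(mean(lg[a, j]) - mean(lg[!a, j])), 3 * se)
  }
  se2 <- sqrt(var(lg[a, 2]) / sum(a) + var(lg[!a, 2]) / sum(!a))
  expect_lt(abs(mean(lg[a, 2]) - mean(lg[!a, 2]) - effect * 0.5), 3 * se2)
})

test_that("a planted standardized effect of 2 is essentially always detectable", {
  hits <- 0
  for (s in 1:50) {
    spec <- layer_spec("amino_acid", 3, detect_prob = 1)
    meta <- small_meta(200)
    tb <- sample_amino_acid_layer(spec, meta,
                                  planted = list(planted_signal("amino_acid", 1,
                                                                c("CRC", "control"), 2)),
                                  seed = 100 + s)
    a <- meta$group == "CRC"
    p <- welch_t_test(log(tb$values[a, 1]), log(tb$values[!a, 1]))$p_value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 48)
})

test_that("null cohorts give nominal Welch type-I error across features", {
  spec <- layer_spec("amino_acid", 500, detect_prob = 1, sdlog = 0.5)
  meta <- small_meta(41, seed = 3)
  meta$group <- rep(c("CRC", "control"), c(21, 20))
  tb <- sample_amino_acid_layer(spec, meta, seed = 55)
  a <- meta$group == "CRC"
  pv <- vapply(seq_len(500), function(j)
    welch_t_test(tb$values[a, j], tb$values[!a, j])$p_value, 0)
  rate <- mean(pv < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("latent factors induce the recorded correlation and vanish at zero variance", {
  spec <- layer_spec("amino_acid", 4, detect_prob = 1)
  meta <- small_meta(60)
  tb <- sample_amino_acid_layer(spec, meta, seed = 61)
  fac <- latent_factor(data.frame(layer_name = "amino_acid",
                                  feature_index = c(1, 2),
                                  loading = c(sqrt(0.6), sqrt(0.6))))
  out <- inject_latent_factors(list(amino_acid = tb), list(fac), seed = 62)
  expect_equal(out$expected_edges$expected_r, 0.6, tolerance = 1e-12)
  r <- cor(log(out$tables$amino_acid$values[, 1]),
           log(out$tables$amino_acid$values[, 2]))
  expect_gt(r, 0.45)  # Fisher-z 99% band for r = 0.6 at n = 60
  expect_lt(r, 0.75)

  null_fac <- latent_factor(data.frame(layer_name = "amino_acid",
                                       feature_index = c(3, 4),
                                       loading = c(0.9, 0.9)),
                            factor_variance = 0)
  out2 <- inject_latent_factors(list(amino_acid = tb), list(null_fac), seed = 63)
  expect_identical(out2$tables$amino_acid$values, tb$values)

  # disjoint factors record no cross-factor edge
  f1 <- latent_factor(data.frame(layer_name = "amino_acid", feature_index = 1:2,
                                 loading = c(0.7, 0.7)))
  f2 <- latent_factor(data.frame(layer_name = "amino_acid", feature_index = 3:4,
                                 loading = c(0.7, 0.7)))
  out3 <- inject_latent_factors(list(amino_acid = tb), list(f1, f2), seed = 64)
  expect_equal(nrow(out3$expected_edges), 2)
  expect_false(any(out3$expected_edges$feature_a == "AA1" &
                     out3$expected_edges$feature_b %in% c("AA3", "AA4")))
})

test_that("empirical latent-pair correlation converges to the recorded value", {
  spec <- layer_spec("amino_acid", 2, detect_prob = 1, sdlog = 0.4)
  meta <- small_meta(2000)
  tb <- sample_amino_acid_layer(spec, meta, seed = 71)
  fac <- latent_factor(data.frame(layer_name = "amino_acid", feature_index = 1:2,
                                  loading = c(0.8, 0.75)))
  out <- inject_latent_factors(list(amino_acid = tb), list(fac), seed = 72)
  target <- out$expected_edges$expected_r
  r <- cor(log(out$tables$amino_acid$values[, 1]),
           log(out$tables$amino_acid$values[, 2]))
  z <- abs(atanh(r) - atanh(target)) * sqrt(2000 - 3)
  expect_lt(z, qnorm(0.995))  # Fisher-z test does not reject at 1%
})

test_that("write_cohort emits one TSV per layer plus metadata and truth", {
  d <- cohort_design(group_sizes = c(CRC = 3, control = 3),
                     layers = list(layer_spec("amino_acid", 5)),
                     planted = list(planted_signal("amino_acid", 1,
                                                   c("CRC", "control"), 1)),
                     seed = 5)
  co <- generate_cohort(d)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("amino_acid.tsv", "metadata.tsv",
                                               "truth_planted.tsv", "truth_edges.tsv")))))
  back <- read_feature_table(file.path(dir, "amino_acid.tsv"), "amino_acid",
                             value_kind = "concentration")
  expect_equal(back$values, co$tables$amino_acid$values, tolerance = 1e-12)
})
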