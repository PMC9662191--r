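#' Specify one synthetic omics layer
#'
#' @param layer_name `"microbiota"`, `"proteome"` or `"amino_acid"`.
#' @param n_features number of features.
#' @param depth_location median per-sample total count (count layers);
#'   totals are drawn log-normally around it.
#' @param depth_dispersion log-scale SD of the per-sample totals.
#' @param overdispersion nonnegative; for the microbiota layer the
#'   Dirichlet overdispersion (counts are Dirichlet-multinomial with
#'   concentration `baseline / overdispersion`; 0 = multinomial), for the
#'   proteome layer the beta-binomial intra-class correlation (0 = binomial).
#' @param baseline_profile feature-level baseline relative abundances
#'   (count layers) or log-scale means (amino acids); defaults to a Zipf
#'   rank-abundance profile (counts) or a spread of log-concentrations.
#' @param sdlog per-feature log-scale SD for the amino-acid layer (recycled).
#' @param detect_prob per-feature probability that an amino acid is
#'   quantified in a sample (missing values are recorded as 0); defaults to
#'   a linear ramp whose sum is ~26 quantified AAs per sample.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(layer_name = c("microbiota", "proteome", "amino_acid"),
                       n_features,
                       depth_location = NULL, depth_dispersion = 0.3,
                       overdispersion = 0, baseline_profile = NULL,
                       sdlog = 0.6, detect_prob = NULL) {
  layer_name <- match.arg(layer_name)
  stopifnot(n_features >= 1, overdispersion >= 0)
  if (layer_name %in% c("microbiota", "proteome")) {
    if (is.null(depth_location)) depth_location <- if (layer_name == "microbiota") 23041 else 1500
    if (depth_location <= 0) stop("count layers need a strictly positive expected depth")
    if (is.null(baseline_profile)) {
      s <- if (layer_name == "microbiota") 1.0 else 0.9
      w <- seq_len(n_features)^(-s)
      baseline_profile <- if (layer_name == "microbiota") w / sum(w) else w / sum(w) * 0.9
    }
  } else {
    if (any(sdlog <= 0)) stop("negative or zero variance parameter for amino-acid layer")
    if (is.null(baseline_profile))
      baseline_profile <- seq(log(2), log(400), length.out = n_features)
    if (is.null(detect_prob))
      detect_prob <- seq(0.98, 0.20, length.out = n_features)
    detect_prob <- rep_len(detect_prob, n_features)
    sdlog <- rep_len(sdlog, n_features)
  }
  if (length(baseline_profile) != n_features)
    stop("baseline_profile length (", length(baseline_profile),
         ") must equal n_features (", n_features, ")")
  structure(list(layer_name = layer_name, n_features = n_features,
                 depth_location = depth_location, depth_dispersion = depth_dispersion,
                 overdispersion = overdispersion, baseline_profile = baseline_profile,
                 sdlog = sdlog, detect_prob = detect_prob),
            class = "layer_spec")
}

#' Plant a group effect on one synthetic feature
#'
#' @param layer_name layer the feature lives in.
#' @param feature_index 1-based index of the feature within the layer.
#' @param contrast ordered pair of group labels; the effect is applied to
#'   samples of `contrast[1]` relative to `contrast[2]`.
#' @param effect_size log-fold change for count layers (taxon baseline
#'   abundance or protein proportion is multiplied by `exp(effect_size)`);
#'   standardized log-scale mean shift for the amino-acid layer (the shift
#'   applied is `effect_size * sdlog` of that feature).
#' @return An object of class `planted_signal`.
#' @export
planted_signal <- function(layer_name, feature_index, contrast, effect_size) {
  stopifnot(length(contrast) == 2, is.numeric(effect_size), length(feature_index) == 1)
  structure(list(layer_name = layer_name, feature_index = as.integer(feature_index),
                 contrast = as.character(contrast), effect_size = effect_size),
            class = "planted_signal")
}

#' Specify a latent factor inducing known cross-layer correlations
#'
#' A per-sample standard-normal factor scaled by `sqrt(factor_variance)`
#' perturbs the loaded features on their log analysis scale, replacing each
#' standardized column `z` by `sqrt(1 - w^2) z + w f` with effective loading
#' `w = loading * sqrt(factor_variance)`. Any two features loaded on the
#' same factor then have expected (log-scale) correlation `w_i * w_j`,
#' recorded as ground truth for network recovery.
#'
#' @param loadings data frame with columns `layer_name`, `feature_index`,
#'   `loading`; effective loadings must satisfy `|loading| * sqrt(factor_variance) < 1`.
#' @param factor_variance nonnegative factor variance; 0 leaves tables
#'   unchanged.
#' @return An object of class `latent_factor`.
#' @export
latent_factor <- function(loadings, factor_variance = 1) {
  stopifnot(is.data.frame(loadings),
            all(c("layer_name", "feature_index", "loading") %in% names(loadings)),
            factor_variance >= 0)
  w <- abs(loadings$loading) * sqrt(factor_variance)
  if (any(w >= 1))
    stop("effective loading |loading|*sqrt(factor_variance) must be < 1")
  structure(list(loadings = loadings, factor_variance = factor_variance),
            class = "latent_factor")
}

#' Design a synthetic matched case-control multi-omics cohort
#'
#' The defaults emulate the study conditions of the emulated cohort:
#' 12 CRC / 21 adenoma / 20 control samples; 225 taxa with median
#' sequencing depth 23,041; 521 proteins with a median of ~169 detected per
#' sample; 44 amino acids with a median of ~26 quantified per sample.
#' Covariates (age, sex, BMI, smoking) are drawn balanced across groups,
#' mimicking a matched design; downstream models use features only.
#'
#' @param group_sizes named integer vector of per-group sample counts
#'   (each >= 2).
#' @param layers list of [layer_spec()] objects.
#' @param planted list of [planted_signal()] objects.
#' @param latent_factors list of [latent_factor()] objects.
#' @param seed integer root seed; a fixed seed makes the generated cohort
#'   bit-reproducible. Per-layer substream seeds are derived from it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(CRC = 12, adenoma = 21, control = 20),
                          layers = list(layer_spec("microbiota", 225),
                                        layer_spec("proteome", 521, overdispersion = 0.005),
                                        layer_spec("amino_acid", 44)),
                          planted = list(), latent_factors = list(), seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector")
  if (any(group_sizes < 2)) stop("every group needs at least 2 samples")
  layer_names <- vapply(layers, function(l) l$layer_name, "")
  if (anyDuplicated(layer_names)) stop("duplicate layer in design")
  for (p in planted) {
    if (!p$layer_name %in% layer_names)
      stop("planted signal references unknown layer '", p$layer_name, "'")
    k <- layers[[match(p$layer_name, layer_names)]]$n_features
    if (p$feature_index < 1 || p$feature_index > k)
      stop("planted signal references feature index ", p$feature_index,
           " outside layer '", p$layer_name, "' (", k, " features)")
    if (!all(p$contrast %in% names(group_sizes)))
      stop("planted signal contrast uses unknown group(s): ",
           paste(setdiff(p$contrast, names(group_sizes)), collapse = ", "))
  }
  for (fct in latent_factors) {
    for (i in seq_len(nrow(fct$loadings))) {
      ln <- fct$loadings$layer_name[i]
      if (!ln %in% layer_names)
        stop("latent factor loading references unknown layer '", ln, "'")
      k <- layers[[match(ln, layer_names)]]$n_features
      if (fct$loadings$feature_index[i] < 1 || fct$loadings$feature_index[i] > k)
        stop("latent factor loading references feature index ",
             fct$loadings$feature_index[i], " outside layer '", ln, "'")
    }
  }
  structure(list(group_sizes = group_sizes, layers = layers, planted = planted,
                 latent_factors = latent_factors, seed = as.integer(seed)),
            class = "cohort_design")
}

feature_id_prefix <- c(microbiota = "OTU", proteome = "PROT", amino_acid = "AA")

make_feature_ids <- function(layer_name, n) {
  ids <- sprintf("%s%0*d", feature_id_prefix[[layer_name]], nchar(as.character(n)), seq_len(n))
  if (layer_name == "proteome" && n >= 4) {
    # synthetic stand-ins for the hemoglobin subunits used as the FIT-like
    # reference panel; placed on the most abundant baseline ranks
    ids[1:4] <- c("HBA1", "HBB", "HBD.HBE1", "HBG2.HBG1")
  }
  ids
}

draw_positive_totals <- function(n, location, dispersion) {
  tot <- round(stats::rlnorm(n, meanlog = log(location), sdlog = dispersion))
  while (any(tot == 0))  # never emit an all-zero sample
    tot[tot == 0] <- round(stats::rlnorm(sum(tot == 0), log(location), dispersion))
  tot
}

planted_multipliers <- function(spec, groups, planted) {
  # n_samples x n_features multiplier matrix exp(effect) applied to baseline
  mult <- matrix(1, length(groups), spec$n_features)
  for (p in planted) {
    if (p$layer_name != spec$layer_name) next
    hit <- groups == p$contrast[1]
    mult[hit, p$feature_index] <- mult[hit, p$feature_index] * exp(p$effect_size)
  }
  mult
}

#' Sample a synthetic 16S microbiota count layer
#'
#' Per-sample totals are log-normal around `depth_location`;
#' compositions are Dirichlet-multinomial with concentration
#' `baseline / overdispersion` (multinomial when overdispersion is 0).
#' Planted log-fold effects multiply the baseline abundances of the target
#' group before renormalization, so induced effects are compositional.
#'
#' @param spec a [layer_spec()] with `layer_name = "microbiota"`.
#' @param meta a [cohort_metadata()] giving sample IDs and groups.
#' @param planted list of [planted_signal()] objects (other layers ignored).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A count [feature_table()].
#' @export
sample_microbiome_layer <- function(spec, meta, planted = list(), seed = NULL) {
  stopifnot(spec$layer_name == "microbiota")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(meta)
  totals <- draw_positive_totals(n, spec$depth_location, spec$depth_dispersion)
  mult <- planted_multipliers(spec, meta$group, planted)
  base <- spec$baseline_profile / sum(spec$baseline_profile)
  x <- matrix(0L, n, spec$n_features)
  for (j in seq_len(n)) {
    pj <- base * mult[j, ]
    pj <- pj / sum(pj)
    if (spec$overdispersion > 0) {
      g <- stats::rgamma(spec$n_features, shape = pj / spec$overdispersion)
      while (sum(g) == 0)
        g <- stats::rgamma(spec$n_features, shape = pj / spec$overdispersion)
      pj <- g / sum(g)
    }
    x[j, ] <- stats::rmultinom(1, totals[j], pj)[, 1]
  }
  dimnames(x) <- list(meta$sample_id, make_feature_ids("microbiota", spec$n_features))
  feature_table(x, "microbiota", "count")
}

#' Sample a synthetic proteome spectral-count layer
#'
#' Per-sample total spectra are log-normal around `depth_location`; each
#' protein's count is beta-binomial given the sample total with baseline
#' proportion from `baseline_profile` and intra-class correlation
#' `overdispersion` (binomial at 0). Planted effects multiply the
#' underlying proportion for the target group.
#'
#' @inheritParams sample_microbiome_layer
#' @return A count [feature_table()].
#' @export
sample_proteome_layer <- function(spec, meta, planted = list(), seed = NULL) {
  stopifnot(spec$layer_name == "proteome")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(meta)
  totals <- draw_positive_totals(n, spec$depth_location, spec$depth_dispersion)
  mult <- planted_multipliers(spec, meta$group, planted)
  phi <- spec$overdispersion
  x <- matrix(0L, n, spec$n_features)
  for (j in seq_len(n)) {
    pj <- pmin(spec$baseline_profile * mult[j, ], 0.99)
    if (phi > 0) {
      a <- pj * (1 - phi) / phi
      b <- (1 - pj) * (1 - phi) / phi
      pj <- stats::rbeta(spec$n_features, a, b)
    }
    x[j, ] <- stats::rbinom(spec$n_features, totals[j], pj)
  }
  dimnames(x) <- list(meta$sample_id, make_feature_ids("proteome", spec$n_features))
  feature_table(x, "proteome", "count")
}

#' Sample a synthetic amino-acid concentration layer
#'
#' Concentrations are log-normal per feature with log-means from
#' `baseline_profile` and log-SDs `sdlog`; planted standardized shifts are
#' applied on the log scale. A missing-at-random quantification mask
#' (per-feature detection probabilities `detect_prob`) records
#' unquantified amino acids as 0.
#'
#' @inheritParams sample_microbiome_layer
#' @return A concentration [feature_table()].
#' @export
sample_amino_acid_layer <- function(spec, meta, planted = list(), seed = NULL) {
  stopifnot(spec$layer_name == "amino_acid")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(meta)
  shift <- matrix(0, n, spec$n_features)
  for (p in planted) {
    if (p$layer_name != spec$layer_name) next
    hit <- meta$group == p$contrast[1]
    shift[hit, p$feature_index] <- shift[hit, p$feature_index] +
      p$effect_size * spec$sdlog[p$feature_index]
  }
  x <- matrix(stats::rlnorm(n * spec$n_features,
                            meanlog = rep(spec$baseline_profile, each = n) + shift,
                            sdlog = rep(spec$sdlog, each = n)),
              n, spec$n_features)
  mask <- matrix(stats::rbinom(n * spec$n_features, 1,
                               rep(spec$detect_prob, each = n)),
                 n, spec$n_features)
  x <- x * mask
  dimnames(x) <- list(meta$sample_id, make_feature_ids("amino_acid", spec$n_features))
  feature_table(x, "amino_acid", "concentration")
}

analysis_scale <- function(values, value_kind) {
  if (value_kind == "normalized") values else log1p(values)
}

from_analysis_scale <- function(y, value_kind) {
  if (value_kind == "normalized") return(y)
  x <- expm1(y)
  x[x < 0] <- 0
  if (value_kind == "count") x <- round(x)
  x
}

#' Inject latent factors into generated tables
#'
#' See [latent_factor()] for the perturbation model. Count layers are
#' perturbed on the `log1p` scale and rounded back; the expected log-scale
#' correlation of each within-factor feature pair is returned as ground
#' truth for network recovery.
#'
#' @param tables named list of [feature_table()] objects.
#' @param factors list of [latent_factor()] objects.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return List with `tables` (perturbed) and `expected_edges` (data frame
#'   `feature_a, layer_a, feature_b, layer_b, expected_r`).
#' @export
inject_latent_factors <- function(tables, factors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layer_names <- vapply(tables, function(tb) tb$layer, "")
  names(tables) <- layer_names
  edges <- list()
  loaded_once <- character()
  for (fct in factors) {
    if (fct$factor_variance == 0) next
    sigma <- sqrt(fct$factor_variance)
    n <- nrow(tables[[1]]$values)
    f <- stats::rnorm(n)
    L <- fct$loadings
    key <- paste(L$layer_name, L$feature_index)
    clash <- intersect(key, loaded_once)
    if (length(clash))
      stop("feature loaded by more than one latent factor: ", clash[1])
    loaded_once <- c(loaded_once, key)
    w <- L$loading * sigma
    ids <- character(nrow(L))
    for (i in seq_len(nrow(L))) {
      tb <- tables[[L$layer_name[i]]]
      if (is.null(tb)) stop("latent factor loading references unknown layer '", L$layer_name[i], "'")
      if (L$feature_index[i] > ncol(tb$values))
        stop("latent factor loading references feature index ", L$feature_index[i],
             " outside layer '", L$layer_name[i], "'")
      y <- analysis_scale(tb$values[, L$feature_index[i]], tb$value_kind)
      m <- mean(y); s <- stats::sd(y)
      if (s == 0)
        stop("cannot load latent factor on zero-variance feature ",
             colnames(tb$values)[L$feature_index[i]])
      z <- (y - m) / s
      z2 <- sqrt(1 - w[i]^2) * z + w[i] * f
      tables[[L$layer_name[i]]]$values[, L$feature_index[i]] <-
        from_analysis_scale(z2 * s + m, tb$value_kind)
      ids[i] <- colnames(tb$values)[L$feature_index[i]]
    }
    if (nrow(L) >= 2) {
      pr <- utils::combn(nrow(L), 2)
      edges[[length(edges) + 1L]] <- data.frame(
        feature_a = ids[pr[1, ]], layer_a = L$layer_name[pr[1, ]],
        feature_b = ids[pr[2, ]], layer_b = L$layer_name[pr[2, ]],
        expected_r = w[pr[1, ]] * w[pr[2, ]], stringsAsFactors = FALSE)
    }
  }
  expected_edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(feature_a = character(), layer_a = character(),
               feature_b = character(), layer_b = character(),
               expected_r = numeric(), stringsAsFactors = FALSE)
  list(tables = tables, expected_edges = expected_edges)
}

simulate_covariates <- function(n) {
  data.frame(
    age = pmin(pmax(round(stats::rnorm(n, 68, 7)), 40), 90),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4)),
    bmi = round(stats::rnorm(n, 26, 3), 1),
    smoking = sample(c("never", "stopped", "active"), n, replace = TRUE,
                     prob = c(0.25, 0.6, 0.15)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws one feature table per layer with identical sample IDs, the cohort
#' metadata, and a ground-truth record of every planted group effect and
#' every expected latent-factor correlation. With a fixed `design$seed` the
#' output is bit-reproducible; each layer uses its own RNG substream so
#' layers can be regenerated independently.
#'
#' @param design a [cohort_design()].
#' @return List with `tables` (named list of [feature_table()]), `meta`
#'   (a [cohort_metadata()]) and `truth` (list with `planted` and
#'   `expected_edges` data frames).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  sub <- sample.int(.Machine$integer.max - 1L, length(design$layers) + 2L)
  n <- sum(design$group_sizes)
  set.seed(sub[1])
  meta <- cohort_metadata(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = rep(names(design$group_sizes), design$group_sizes))
  cov <- simulate_covariates(n)
  meta$age <- cov$age; meta$sex <- cov$sex; meta$bmi <- cov$bmi; meta$smoking <- cov$smoking

  samplers <- list(microbiota = sample_microbiome_layer,
                   proteome = sample_proteome_layer,
                   amino_acid = sample_amino_acid_layer)
  tables <- list()
  for (i in seq_along(design$layers)) {
    spec <- design$layers[[i]]
    tables[[spec$layer_name]] <-
      samplers[[spec$layer_name]](spec, meta, design$planted, seed = sub[1 + i])
  }
  inj <- inject_latent_factors(tables, design$latent_factors,
                               seed = sub[length(sub)])
  planted_df <- if (length(design$planted)) do.call(rbind, lapply(design$planted, function(p) {
    tb <- tables[[p$layer_name]]
    data.frame(layer = p$layer_name,
               feature_id = colnames(tb$values)[p$feature_index],
               group_a = p$contrast[1], group_b = p$contrast[2],
               effect_size = p$effect_size, stringsAsFactors = FALSE)
  })) else data.frame(layer = character(), feature_id = character(),
                      group_a = character(), group_b = character(),
                      effect_size = numeric(), stringsAsFactors = FALSE)
  list(tables = inj$tables, meta = meta,
       truth = list(planted = planted_df, expected_edges = inj$expected_edges))
}

#' Write a generated cohort to a directory
#'
#' Writes one TSV per layer, the metadata TSV, and the ground truth
#' (planted signals and expected latent-factor correlations) as TSVs.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in cohort$tables)
    write_feature_table(tb, file.path(dir, paste0(tb$layer, ".tsv")))
  write_metadata(cohort$meta, file.path(dir, "metadata.tsv"))
  utils::write.table(cohort$truth$planted, file.path(dir, "truth_planted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$expected_edges, file.path(dir, "truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
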