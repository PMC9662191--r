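#' Configuration of a two-group comparison run
#'
#' @param groups character pair, e.g. `c("CRC", "control")`; the first
#'   entry is modeled as the positive (case) class.
#' @param penalty a [penalty_config()] for both stability-selection stages.
#' @param min_prevalence sparse-feature filter threshold applied to count
#'   layers before normalization (0 disables; the advanced- vs
#'   non-advanced-adenoma sub-analysis uses 0.2).
#' @param microbiota_relative if TRUE, convert microbiota counts to
#'   relative abundances before autoscaling (the normalization is otherwise
#'   applied to raw values).
#' @param n_eval_iterations iterations for bootstrap and permuted-label
#'   AUC distributions (default 100).
#' @param r_min,p_max network edge thresholds.
#' @param reference_ids reference (hemoglobin-subunit) panel IDs for the
#'   FIT-like comparison; skipped if absent from the proteome layer.
#' @param pca_components PCA components summarized per layer.
#' @param seed mandatory integer root seed; stage-indexed substreams are
#'   derived from it so stages are independently re-runnable.
#' @return Object of class `comparison_config`.
#' @export
comparison_config <- function(groups, penalty = penalty_config(),
                              min_prevalence = 0, microbiota_relative = FALSE,
                              n_eval_iterations = 100,
                              r_min = 0.3, p_max = 0.05,
                              reference_ids = c("HBA1", "HBB", "HBD.HBE1", "HBG2.HBG1"),
                              pca_components = 2, seed) {
  if (missing(seed)) stop("a seed is mandatory for a comparison run")
  stopifnot(length(groups) == 2, is.numeric(seed))
  structure(list(groups = as.character(groups), penalty = penalty,
                 min_prevalence = min_prevalence,
                 microbiota_relative = isTRUE(microbiota_relative),
                 n_eval_iterations = n_eval_iterations,
                 r_min = r_min, p_max = p_max, reference_ids = reference_ids,
                 pca_components = pca_components, seed = as.integer(seed)),
            class = "comparison_config")
}

#' Read a comparison configuration from YAML
#'
#' Recognized keys mirror the arguments of [comparison_config()]; the
#' `penalty` block holds [penalty_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `comparison_config`.
#' @export
read_comparison_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || length(cfg$groups) != 2)
    stop("config must name exactly two groups")
  if (is.null(cfg$seed)) stop("config must set a seed")
  pen <- do.call(penalty_config, c(cfg$penalty, if (is.null(cfg$penalty$seed))
    list(seed = cfg$seed)))
  args <- cfg[setdiff(names(cfg), "penalty")]
  do.call(comparison_config, c(args, list(penalty = pen)))
}

stage_log <- function(log, stage, t0, note = "") {
  rbind(log, data.frame(stage = stage,
                        seconds = round(as.numeric(Sys.time()) - t0, 2),
                        note = note, stringsAsFactors = FALSE))
}

pooled_matrix <- function(tables, features_per_layer) {
  cols <- list()
  for (ln in names(features_per_layer)) {
    f <- features_per_layer[[ln]]
    if (!length(f)) next
    cols[[ln]] <- tables[[ln]]$values[, f, drop = FALSE]
  }
  do.call(cbind, cols)
}

#' Run the full two-group comparison pipeline
#'
#' Executes the end-to-end workflow on one comparison: sample alignment,
#' optional sparse-taxon filtering, autoscaling, per-layer PCA summary,
#' per-layer combined LASSO/EN stability selection with first-quartile
#' retention, per-layer panel evaluation, a pooled second-stage selection
#' over the union of per-layer selections yielding the cross-omics panel,
#' the hemoglobin-subunit reference comparison, and the thresholded
#' cross-omics correlation network. Every random stage is seeded from
#' `config$seed`, so a fixed seed reproduces the report exactly.
#'
#' @param tables named list of [feature_table()] objects (one per layer).
#' @param meta a [cohort_metadata()].
#' @param config a [comparison_config()].
#' @return Object of class `comparison_report`.
#' @export
run_comparison <- function(tables, meta, config) {
  stopifnot(inherits(config, "comparison_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 8 + 2 * length(tables))
  log <- data.frame(stage = character(), seconds = numeric(), note = character(),
                    stringsAsFactors = FALSE)
  t0 <- as.numeric(Sys.time())
  al <- align_samples(tables, meta, config$groups)
  tables <- al$tables
  meta <- al$meta
  y <- factor(meta$group, levels = rev(config$groups))  # positive = groups[1]
  positive <- config$groups[1]
  log <- stage_log(log, "align", t0, sprintf("%d samples", nrow(meta)))

  t0 <- as.numeric(Sys.time())
  norm <- list(); pca <- list()
  for (ln in names(tables)) {
    tb <- tables[[ln]]
    if (config$min_prevalence > 0 && tb$value_kind == "count")
      tb <- filter_sparse_features(tb, config$min_prevalence)
    if (config$microbiota_relative && tb$layer == "microbiota")
      tb <- relative_abundance(tb)
    tb <- suppressWarnings(autoscale(tb))
    norm[[ln]] <- tb
    k <- min(config$pca_components, nrow(tb$values) - 1L, ncol(tb$values))
    pca[[ln]] <- run_pca(tb, n_components = k)
  }
  log <- stage_log(log, "normalize", t0,
                   paste(vapply(norm, function(tb) ncol(tb$values), 0L), collapse = "/"))

  selections <- list(); layer_panels <- list(); selected <- list()
  si <- 0L
  for (ln in names(norm)) {
    t0 <- as.numeric(Sys.time())
    pen <- config$penalty
    pen$seed <- stage_seeds[3 + si]
    sel <- stability_selection(norm[[ln]]$values, y, pen)
    selections[[ln]] <- sel
    selected[[ln]] <- suppressWarnings(select_first_quartile(sel))
    log <- stage_log(log, paste0("stability_", ln), t0,
                     sprintf("%d selected", length(selected[[ln]])))
    if (length(selected[[ln]])) {
      t0 <- as.numeric(Sys.time())
      layer_panels[[ln]] <- evaluate_panel(norm[[ln]]$values, y,
                                           features = selected[[ln]],
                                           n_iterations = config$n_eval_iterations,
                                           seed = stage_seeds[3 + si + length(norm)],
                                           positive = positive)
      log <- stage_log(log, paste0("panel_", ln), t0)
    }
    si <- si + 1L
  }

  t0 <- as.numeric(Sys.time())
  combined <- second_stage_panel(selected, norm, y, config,
                                 seed = stage_seeds[3 + 2 * length(norm)])
  log <- stage_log(log, "second_stage", t0,
                   sprintf("%d features", length(combined$report$features)))

  reference <- NULL
  if ("proteome" %in% names(norm)) {
    present <- intersect(config$reference_ids, colnames(norm$proteome$values))
    if (length(present)) {
      t0 <- as.numeric(Sys.time())
      reference <- reference_panel_auc(norm$proteome, y,
                                       reference_ids = config$reference_ids,
                                       n_iterations = config$n_eval_iterations,
                                       seed = stage_seeds[4 + 2 * length(norm)],
                                       positive = positive)
      log <- stage_log(log, "reference_panel", t0)
    } else {
      log <- stage_log(log, "reference_panel", as.numeric(Sys.time()),
                       "skipped: no reference IDs present")
    }
  }

  t0 <- as.numeric(Sys.time())
  layer_map <- unlist(lapply(names(selected), function(ln)
    stats::setNames(rep(ln, length(selected[[ln]])), selected[[ln]])))
  net <- NULL
  if (length(layer_map)) {
    xsel <- pooled_matrix(norm, selected)
    cm <- suppressWarnings(correlate_selected(xsel, method = "pearson",
                                              layers = layer_map))
    edges <- filter_edges(cm, r_min = config$r_min, p_max = config$p_max)
    net <- build_network(edges,
                         data.frame(feature_id = names(layer_map),
                                    layer = unname(layer_map),
                                    stringsAsFactors = FALSE),
                         thresholds = list(r_min = config$r_min, p_max = config$p_max))
  }
  log <- stage_log(log, "network", t0,
                   if (is.null(net)) "skipped: empty selection" else
                     sprintf("%d edges", nrow(net$edges)))

  structure(list(config = config, meta = meta, pca = pca,
                 selections = selections, selected = selected,
                 layer_panels = layer_panels,
                 combined_panel = combined$report,
                 combined_features = combined$report$features,
                 reference_panel = reference, network = net, log = log),
            class = "comparison_report")
}

#' Pooled second-stage panel selection
#'
#' Re-applies the stability-selection machinery to the pooled, autoscaled
#' matrix over the union of the per-layer selected features, retaining its
#' first quartile as the final cross-omics panel, which is then fit and
#' evaluated. A union of size one is the panel itself; if the second-stage
#' quartile comes back empty the union is used with a log note.
#'
#' @param selected named list (by layer) of selected feature IDs.
#' @param norm_tables named list of normalized [feature_table()] objects.
#' @param y two-level labels.
#' @param config a [comparison_config()].
#' @param seed stage seed (default derived from `config$seed`).
#' @return List with `features` and `report` (a `panel_report`).
#' @export
second_stage_panel <- function(selected, norm_tables, y, config,
                               seed = config$seed) {
  union_size <- sum(lengths(selected))
  if (union_size == 0) stop("empty union of selected features")
  x <- pooled_matrix(norm_tables, selected)
  positive <- config$groups[1]
  if (union_size == 1) {
    features <- colnames(x)
  } else {
    pen <- config$penalty
    pen$seed <- seed
    sel2 <- stability_selection(x, y, pen)
    features <- suppressWarnings(select_first_quartile(sel2))
    if (!length(features)) features <- colnames(x)
  }
  report <- evaluate_panel(x, y, features = features,
                           n_iterations = config$n_eval_iterations,
                           seed = seed + 1L, positive = positive)
  list(features = features, report = report)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s (%d samples)\n",
              x$config$groups[1], x$config$groups[2], nrow(x$meta)))
  for (ln in names(x$selected))
    cat(sprintf("  %-11s %d selected: %s\n", ln, length(x$selected[[ln]]),
                paste(utils::head(x$selected[[ln]], 5), collapse = ", ")))
  cat(sprintf("  combined panel (%d): %s\n", length(x$combined_features),
              paste(x$combined_features, collapse = ", ")))
  cat(sprintf("  combined AUC test/apparent: %.3f / %.3f; permuted-null mean %.3f\n",
              x$combined_panel$auc_test, x$combined_panel$auc_apparent,
              mean(x$combined_panel$null_auc)))
  if (!is.null(x$reference_panel))
    cat(sprintf("  reference (hemoglobin) AUC test: %.3f\n",
                x$reference_panel$auc_test))
  if (!is.null(x$network)) print(x$network)
  invisible(x)
}

#' Write all artifacts of a comparison run
#'
#' Writes per-layer stability TSVs, panel report JSONs (+ AUC TSV
#' sidecars), the edge list and GraphML network, and the run log. All
#' artifacts except `run_log.tsv` are timestamp-free, so a fixed seed
#' reproduces them byte-identically.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ln in names(report$selections))
    write_stability(report$selections[[ln]],
                    file.path(dir, paste0("stability_", ln, ".tsv")), layer = ln)
  for (ln in names(report$layer_panels))
    write_panel_report(report$layer_panels[[ln]],
                       file.path(dir, paste0("panel_", ln, ".json")))
  write_panel_report(report$combined_panel, file.path(dir, "panel_combined.json"))
  if (!is.null(report$reference_panel))
    write_panel_report(report$reference_panel, file.path(dir, "panel_reference.json"))
  if (!is.null(report$network)) {
    write_edges(report$network, file.path(dir, "network_edges.tsv"))
    write_graphml(report$network, file.path(dir, "network.graphml"))
  }
  pca_df <- do.call(rbind, lapply(names(report$pca), function(ln)
    data.frame(layer = ln, component = seq_along(report$pca[[ln]]$explained_variance),
               explained_variance = report$pca[[ln]]$explained_variance,
               stringsAsFactors = FALSE)))
  utils::write.table(pca_df, file.path(dir, "pca_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$log, file.path(dir, "run_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
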