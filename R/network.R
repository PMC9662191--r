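#' Correlation matrices over selected features
#'
#' Computes the full correlation and p-value matrices over the columns of
#' a normalized, cross-layer concatenated matrix of selected features.
#' Pearson and Spearman p-values use the t-transform
#' `t = r sqrt(n-2)/sqrt(1-r^2)` (Spearman on ranks); Kendall's tau-b uses
#' the tie-corrected normal approximation of [stats::cor.test()].
#' Zero-variance features are excluded with a warning.
#'
#' @param x numeric matrix (samples x selected features) or normalized
#'   [feature_table()]; needs >= 4 samples.
#' @param method `"pearson"` (default), `"spearman"` or `"kendall"`.
#' @param layers optional named character vector mapping feature ID to
#'   layer tag, attached to the result for edge building.
#' @return List of class `correlation_matrices` with `r` (symmetric, unit
#'   diagonal), `p`, `method`, `n` and `layers`.
#' @export
correlate_selected <- function(x, method = c("pearson", "spearman", "kendall"),
                               layers = NULL) {
  method <- match.arg(method)
  if (inherits(x, "feature_table")) x <- x$values
  if (nrow(x) < 4) stop("need at least 4 samples to correlate")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  n <- nrow(x)
  k <- ncol(x)
  if (method %in% c("pearson", "spearman")) {
    xx <- if (method == "spearman") apply(x, 2L, rank) else x
    r <- stats::cor(xx)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    r <- diag(1, k)
    p <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ct <- suppressWarnings(stats::cor.test(x[, i], x[, j], method = "kendall",
                                             exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(r) <- 1
  diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(colnames(x), colnames(x))
  structure(list(r = r, p = p, method = method, n = n, layers = layers),
            class = "correlation_matrices")
}

#' Threshold correlations into an edge list
#'
#' Retains each unordered feature pair once if `|r| >= r_min` and
#' `p < p_max`. The magnitude threshold is inclusive and the significance
#' threshold strict, so outputs are bit-reproducible at the boundaries.
#'
#' @param cm a `correlation_matrices` object from [correlate_selected()].
#' @param r_min minimum absolute correlation (default 0.3).
#' @param p_max maximum p-value, exclusive (default 0.05).
#' @return Data frame `feature_a, layer_a, feature_b, layer_b, method, r, p`.
#' @export
filter_edges <- function(cm, r_min = 0.3, p_max = 0.05) {
  ids <- rownames(cm$r)
  k <- length(ids)
  layer_of <- function(f) {
    if (is.null(cm$layers)) NA_character_ else unname(cm$layers[f])
  }
  rows <- list()
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (abs(cm$r[i, j]) >= r_min && cm$p[i, j] < p_max)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_a = ids[i], layer_a = layer_of(ids[i]),
          feature_b = ids[j], layer_b = layer_of(ids[j]),
          method = cm$method, r = cm$r[i, j], p = cm$p[i, j],
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_a = character(), layer_a = character(),
               feature_b = character(), layer_b = character(),
               method = character(), r = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
}

#' Build a cross-omics network from filtered edges
#'
#' Isolated selected features are retained as nodes so panel members stay
#' visible in the network even without significant correlations.
#'
#' @param edges edge data frame from [filter_edges()].
#' @param node_catalog data frame `feature_id, layer` listing every
#'   selected feature.
#' @param thresholds list recording the thresholds used (stored verbatim).
#' @return Object of class `omics_network` with `nodes`, `edges` and
#'   `thresholds`.
#' @export
build_network <- function(edges, node_catalog,
                          thresholds = list(r_min = 0.3, p_max = 0.05)) {
  stopifnot(all(c("feature_id", "layer") %in% names(node_catalog)))
  unknown <- setdiff(unique(c(edges$feature_a, edges$feature_b)),
                     node_catalog$feature_id)
  if (length(unknown))
    stop("edge references feature(s) not in the node catalog: ",
         paste(unknown, collapse = ", "))
  if (any(edges$feature_a == edges$feature_b)) stop("self-loop edge")
  structure(list(nodes = node_catalog[, c("feature_id", "layer")],
                 edges = edges, thresholds = thresholds),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cross <- sum(x$edges$layer_a != x$edges$layer_b, na.rm = TRUE)
  cat(sprintf("<omics_network> %d nodes, %d edges (%d cross-layer); |r| >= %s, p < %s\n",
              nrow(x$nodes), nrow(x$edges), cross,
              format(x$thresholds$r_min), format(x$thresholds$p_max)))
  invisible(x)
}

#' Convert an omics network to igraph / GraphML
#'
#' @param network an `omics_network`.
#' @return An [igraph::graph_from_data_frame()] graph with `layer` as node
#'   attribute and `r` as edge weight.
#' @export
as_igraph <- function(network) {
  verts <- data.frame(name = network$nodes$feature_id,
                      layer = network$nodes$layer, stringsAsFactors = FALSE)
  ed <- network$edges
  if (nrow(ed)) {
    ed <- data.frame(from = ed$feature_a, to = ed$feature_b,
                     weight = ed$r, p = ed$p, method = ed$method,
                     stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(from = character(), to = character(), weight = numeric(),
                     p = numeric(), method = character(), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

#' @rdname as_igraph
#' @param path output GraphML path.
#' @return `write_graphml` returns `path` invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write a network edge list to TSV
#' @param network an `omics_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-method correlation consistency
#'
#' Computes the per-pair correlation and p-value under several methods and
#' the pairwise agreement (Jaccard fraction of thresholded edges shared)
#' between methods.
#'
#' @param x matrix or normalized [feature_table()] of selected features.
#' @param methods at least two of `"pearson"`, `"spearman"`, `"kendall"`.
#' @param r_min,p_max edge thresholds used for the agreement statistic.
#' @param layers optional feature-to-layer map.
#' @return List with `table` (per-pair r and p by method) and `agreement`
#'   (named numeric, one entry per method pair).
#' @export
cross_method_consistency <- function(x, methods = c("pearson", "spearman", "kendall"),
                                     r_min = 0.3, p_max = 0.05, layers = NULL) {
  if (length(methods) < 2) stop("need at least two methods")
  cms <- lapply(methods, function(m) correlate_selected(x, method = m, layers = layers))
  names(cms) <- methods
  ids <- rownames(cms[[1]]$r)
  pr <- utils::combn(length(ids), 2)
  tab <- data.frame(feature_a = ids[pr[1, ]], feature_b = ids[pr[2, ]],
                    stringsAsFactors = FALSE)
  for (m in methods) {
    tab[[paste0("r_", m)]] <- cms[[m]]$r[cbind(pr[1, ], pr[2, ])]
    tab[[paste0("p_", m)]] <- cms[[m]]$p[cbind(pr[1, ], pr[2, ])]
  }
  edge_key <- function(m) {
    e <- filter_edges(cms[[m]], r_min = r_min, p_max = p_max)
    paste(e$feature_a, e$feature_b)
  }
  keys <- lapply(methods, edge_key)
  names(keys) <- methods
  mp <- utils::combn(methods, 2)
  agreement <- apply(mp, 2L, function(pair) {
    a <- keys[[pair[1]]]; b <- keys[[pair[2]]]
    u <- union(a, b)
    if (!length(u)) return(1)
    length(intersect(a, b)) / length(u)
  })
  names(agreement) <- apply(mp, 2L, paste, collapse = "-")
  list(table = tab, agreement = agreement)
}
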