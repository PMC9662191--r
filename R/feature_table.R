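#' Construct a feature table
#'
#' A feature table holds one omics layer's measurements as a numeric matrix
#' with samples in rows and features in columns. Three layers are used
#' throughout: 16S taxon counts (`microbiota`), protein spectral counts
#' (`proteome`) and amino-acid concentrations (`amino_acid`), but any layer
#' name is accepted.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   row and column names (sample and feature IDs).
#' @param layer character scalar naming the omics layer.
#' @param value_kind one of `"count"` (nonnegative integers),
#'   `"concentration"` (nonnegative reals) or `"normalized"` (autoscaled).
#' @return An object of class `feature_table`: a list with elements
#'   `values`, `layer` and `value_kind`.
#' @export
feature_table <- function(values, layer, value_kind = c("count", "concentration", "normalized")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample IDs as rownames and feature IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ID: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicated feature ID: ", colnames(values)[duplicated(colnames(values))][1])
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries")
  if (value_kind == "count") {
    if (any(values < 0) || any(values != round(values)))
      stop("count tables must contain nonnegative integers")
  }
  structure(list(values = values, layer = as.character(layer)[1], value_kind = value_kind),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> layer '%s' (%s): %d samples x %d features\n",
              x$layer, x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Sample and feature identifiers of a feature table
#' @param x a [feature_table()].
#' @return character vector of IDs.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Read a feature table from TSV
#'
#' Reads a tab-delimited table with feature IDs in the first column and
#' sample IDs in the header (the QIIME-style export orientation, the
#' default), or the transpose. Values must parse as numbers.
#'
#' @param path file path.
#' @param layer layer name to tag the table with.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param value_kind passed to [feature_table()].
#' @return A [feature_table()] with samples in rows.
#' @export
read_feature_table <- function(path, layer,
                               orientation = c("features_in_rows", "samples_in_rows"),
                               value_kind = "count") {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (length(lines) < 2) stop("feature table '", path, "' has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- length(fields[[1]])
  bad <- which(lengths(fields) != ncol_expect)
  if (length(bad))
    stop("ragged row in '", path, "' at line ", bad[1],
         " (expected ", ncol_expect, " fields, got ", lengths(fields)[bad[1]], ")")
  header <- fields[[1]][-1]
  row_ids <- vapply(fields[-1], `[[`, "", 1L)
  cells <- lapply(fields[-1], function(f) f[-1])
  num <- suppressWarnings(lapply(cells, as.numeric))
  for (i in seq_along(num)) {
    if (anyNA(num[[i]])) {
      j <- which(is.na(num[[i]]))[1]
      stop("non-numeric cell '", cells[[i]][j], "' in '", path, "' at line ", i + 1L,
           ", column ", j + 1L)
    }
  }
  m <- do.call(rbind, num)
  rownames(m) <- row_ids
  colnames(m) <- header
  if (orientation == "features_in_rows") m <- t(m)
  if (value_kind == "count" && all(m == round(m)) && max(abs(m)) < .Machine$integer.max)
    storage.mode(m) <- "integer"
  feature_table(m, layer = layer, value_kind = value_kind)
}

#' Write a feature table to TSV
#'
#' @param x a [feature_table()].
#' @param path output file path.
#' @param orientation orientation to write; default `"features_in_rows"`
#'   (feature IDs in the first column) for symmetry with
#'   [read_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path,
                                orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "features_in_rows") t(x$values) else x$values
  id_col <- if (orientation == "features_in_rows") "feature_id" else "sample_id"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(v) paste(format(v, trim = TRUE, scientific = FALSE, digits = 15),
                                         collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a BIOM v1 (JSON) table
#'
#' Minimal reader for the BIOM v1 dense/sparse JSON format as exported for
#' 16S feature tables.
#'
#' @param path path to a BIOM v1 JSON file.
#' @param layer layer name (default `"microbiota"`).
#' @return A [feature_table()] with samples in rows.
#' @export
read_biom_table <- function(path, layer = "microbiota") {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feat <- vapply(b$rows, function(r) r$id, "")
  samp <- vapply(b$columns, function(cl) cl$id, "")
  m <- matrix(0, length(feat), length(samp), dimnames = list(feat, samp))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
  } else {
    for (trip in b$data) m[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
  }
  kind <- if (all(m == round(m))) "count" else "concentration"
  feature_table(t(m), layer = layer, value_kind = kind)
}

#' Cohort metadata
#'
#' @param sample_id character vector of sample IDs.
#' @param group group labels; must be drawn from the closed vocabulary
#'   `CRC`, `adenoma`, `control`, `advanced_adenoma`, `nonadvanced_adenoma`.
#' @param age,bmi numeric covariates (years, kg/m2).
#' @param sex,smoking character covariates.
#' @return A `data.frame` of class `cohort_metadata`.
#' @export
cohort_metadata <- function(sample_id, group, age = NA_real_, sex = NA_character_,
                            bmi = NA_real_, smoking = NA_character_) {
  vocab <- c("CRC", "adenoma", "control", "advanced_adenoma", "nonadvanced_adenoma")
  group <- as.character(group)
  if (!all(group %in% vocab))
    stop("unknown group label(s): ", paste(setdiff(unique(group), vocab), collapse = ", "))
  if (anyDuplicated(sample_id))
    stop("duplicated sample ID in metadata: ", sample_id[duplicated(sample_id)][1])
  out <- data.frame(sample_id = as.character(sample_id), group = group,
                    age = age, sex = as.character(sex), bmi = bmi,
                    smoking = as.character(smoking), stringsAsFactors = FALSE)
  class(out) <- c("cohort_metadata", "data.frame")
  out
}

#' Read cohort metadata from TSV
#'
#' Expects the header `sample_id  group  age  sex  bmi  smoking`
#' (tab-separated).
#'
#' @param path file path.
#' @return A [cohort_metadata()] data frame.
#' @export
read_metadata <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group", "age", "sex", "bmi", "smoking")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  cohort_metadata(d$sample_id, d$group, d$age, d$sex, d$bmi, d$smoking)
}

#' Write cohort metadata to TSV
#' @param meta a [cohort_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict tables and metadata to shared samples of a two-group comparison
#'
#' Keeps the intersection of sample IDs present in every table and in the
#' metadata, restricted to the two requested groups, and puts every table
#' and the metadata in the same row order. Samples dropped because they are
#' absent from some table are reported via `message()`.
#'
#' @param tables list of [feature_table()] objects.
#' @param meta a [cohort_metadata()].
#' @param groups character vector of length 2 naming the comparison groups.
#' @return List with elements `tables` (same shape as input) and `meta`.
#' @export
align_samples <- function(tables, meta, groups) {
  stopifnot(length(groups) == 2)
  absent <- setdiff(groups, meta$group)
  if (length(absent))
    stop("group(s) not present in metadata: ", paste(absent, collapse = ", "))
  keep_meta <- meta[meta$group %in% groups, , drop = FALSE]
  shared <- Reduce(intersect, c(list(keep_meta$sample_id), lapply(tables, sample_ids)))
  if (length(shared) == 0) stop("no samples shared by all tables and the metadata")
  dropped <- setdiff(keep_meta$sample_id, shared)
  if (length(dropped))
    message("align_samples: dropped ", length(dropped), " sample(s) absent from some table: ",
            paste(dropped, collapse = ", "))
  keep_meta <- keep_meta[match(shared, keep_meta$sample_id), , drop = FALSE]
  n_per_group <- table(factor(keep_meta$group, levels = groups))
  if (any(n_per_group == 0))
    stop("no samples left for group: ", paste(groups[n_per_group == 0], collapse = ", "))
  tables <- lapply(tables, function(tb) {
    tb$values <- tb$values[shared, , drop = FALSE]
    tb
  })
  rownames(keep_meta) <- NULL
  list(tables = tables, meta = keep_meta)
}
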