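#' Feature-by-sample omics matrix with sample metadata
#'
#' The common container for every stage of the pipeline: a numeric matrix
#' (features in rows, samples in columns), a sample metadata data frame, and a
#' layer tag recording the measurement scale.
#'
#' @param values Numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param metadata Data frame with a `sample_id` column covering every column
#'   of `values`; typically also `cell_type`, `condition`, `replicate` or a
#'   two-level `group` factor for cohort designs.
#' @param layer One of `"fpkm"` (non-negative abundance scale), `"lognorm"`
#'   (log2(FPKM+1), possibly quantile-normalized) or `"protein"` (normalized
#'   log protein abundance).
#' @return An object of class `OmicsMatrix`.
#' @export
omics_matrix <- function(values, metadata, layer = c("fpkm", "lognorm", "protein")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values)))) {
    stop("`values` must have unique rownames (feature ids)", call. = FALSE)
  }
  if (nrow(values) == 0 && is.null(rownames(values))) {
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` must have unique colnames (sample ids)", call. = FALSE)
  }
  if (!is.data.frame(metadata) || is.null(metadata$sample_id)) {
    stop("`metadata` must be a data frame with a `sample_id` column", call. = FALSE)
  }
  missing_meta <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing_meta) > 0) {
    stop("metadata missing samples: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  if (layer == "fpkm" && nrow(values) > 0 && any(values < 0)) {
    stop("fpkm layer values must be non-negative", call. = FALSE)
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(
    list(values = values, metadata = metadata, layer = layer),
    class = "OmicsMatrix"
  )
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s]: %d features x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  grp <- intersect(c("cell_type", "condition", "group"), names(x$metadata))
  if (length(grp) > 0) {
    tab <- table(x$metadata[grp])
    cat("sample design:\n")
    print(tab)
  }
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' Subset an OmicsMatrix by features and/or samples
#'
#' @param x An `OmicsMatrix`.
#' @param features,samples Row / column selectors (ids, indices or logical).
#' @return An `OmicsMatrix` with metadata subset accordingly.
#' @export
subset_omics <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "OmicsMatrix"))
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  omics_matrix(v, x$metadata[x$metadata$sample_id %in% colnames(v), , drop = FALSE],
               layer = x$layer)
}

#' Write / read an OmicsMatrix as TSV
#'
#' The matrix TSV carries a `#layer=` comment line, then a header with
#' `feature_id` followed by sample ids. Metadata is written next to it as
#' `<stem>.meta.tsv`.
#'
#' @param x An `OmicsMatrix`.
#' @param path Path of the matrix TSV; metadata goes to `<path minus .tsv>.meta.tsv`.
#' @return `write_omics` returns `path` invisibly; `read_omics` returns an
#'   `OmicsMatrix`.
#' @export
write_omics <- function(x, path) {
  stopifnot(inherits(x, "OmicsMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#layer=", x$layer), con)
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- sub("\\.tsv$", "", path)
  utils::write.table(x$metadata, paste0(meta_path, ".meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics
#' @export
read_omics <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#layer=", first)) {
    stop(sprintf("%s:1: expected a '#layer=' header line", path), call. = FALSE)
  }
  layer <- sub("^#layer=", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (names(df)[1] != "feature_id") {
    stop(sprintf("%s:2: first column must be 'feature_id'", path), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    stop(sprintf("%s: non-numeric abundance values", path), call. = FALSE)
  }
  rownames(vals) <- df$feature_id
  meta_path <- paste0(sub("\\.tsv$", "", path), ".meta.tsv")
  if (!file.exists(meta_path)) {
    stop(sprintf("missing metadata file %s", meta_path), call. = FALSE)
  }
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  omics_matrix(vals, meta, layer = layer)
}

#' Linear-interpolation percentile
#'
#' The single percentile convention used everywhere a cutoff is derived
#' (fold-change, gap, Dice): linear interpolation between order statistics,
#' with `pct` on the 0-100 scale.
#'
#' @param x Numeric vector.
#' @param pct Percentile in `[0, 100]`.
#' @return The interpolated percentile value.
#' @export
percentile <- function(x, pct) {
  unname(stats::quantile(x, probs = pct / 100, type = 7, names = FALSE))
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
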