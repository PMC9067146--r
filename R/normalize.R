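#' Filter features by the expressed criterion
#'
#' Two literal filter modes are provided because the two study designs state
#' different rules: `all_min` keeps features whose value is `>= threshold` in
#' every sample (cell-line comparisons); `majority` keeps features whose value
#' is strictly `> threshold` in strictly more than `majority_frac` of the
#' samples (large-cohort comparisons).
#'
#' @param x An `OmicsMatrix` with layer `"fpkm"`.
#' @param mode `"all_min"` or `"majority"`.
#' @param threshold Expression threshold (FPKM scale), default 1.
#' @param majority_frac Required sample fraction for `majority` mode.
#' @return The filtered `OmicsMatrix` (feature order preserved, samples
#'   unchanged).
#' @export
filter_expressed <- function(x, mode = c("all_min", "majority"),
                             threshold = 1, majority_frac = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "OmicsMatrix"))
  if (x$layer != "fpkm") {
    stop("filter_expressed requires the fpkm layer, got '", x$layer, "'",
         call. = FALSE)
  }
  keep <- if (mode == "all_min") {
    apply(x$values >= threshold, 1, all)
  } else {
    rowMeans(x$values > threshold) > majority_frac
  }
  omics_matrix(x$values[keep, , drop = FALSE], x$metadata, layer = "fpkm")
}

#' log2(FPKM + 1) transformation
#'
#' @param x An `OmicsMatrix` with layer `"fpkm"` (values >= 0).
#' @return An `OmicsMatrix` with layer `"lognorm"`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "OmicsMatrix"))
  if (x$layer != "fpkm") {
    stop("log_transform requires the fpkm layer, got '", x$layer, "'",
         call. = FALSE)
  }
  if (nrow(x$values) > 0 && any(x$values < 0)) {
    stop("negative values are outside the log2(v + 1) domain", call. = FALSE)
  }
  omics_matrix(log2(x$values + 1), x$metadata, layer = "lognorm")
}

#' Quantile normalization
#'
#' Forces every sample to the common reference distribution (the mean of the
#' per-rank sorted values); tied values within a sample receive the mean of
#' the reference values spanning their rank range. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x An `OmicsMatrix` (any layer); at least 2 samples, no missing
#'   values.
#' @return An `OmicsMatrix` of the same layer (fpkm input becomes `lognorm`
#'   only via [log_transform()]; this function does not change the layer).
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "OmicsMatrix"))
  if (ncol(x$values) < 2) {
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(x$values)) {
    stop("missing values are not allowed (no silent imputation)", call. = FALSE)
  }
  if (nrow(x$values) <= 1) {
    # degenerate: every entry becomes the (single) row mean
    v <- matrix(rowMeans(x$values), nrow(x$values), ncol(x$values))
  } else {
    v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  }
  dimnames(v) <- dimnames(x$values)
  out_layer <- if (x$layer == "fpkm") "fpkm" else x$layer
  omics_matrix(v, x$metadata, layer = out_layer)
}
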