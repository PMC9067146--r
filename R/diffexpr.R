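# t-statistic sentinel for the zero-variance, unequal-means guard; exceeds
# any finite Welch t the pooled null can contain on these data scales.
T_SENTINEL <- 1e6

#' Specify a two-group comparison
#'
#' @param group_a,group_b Disjoint sample-id vectors (treated vs control, or
#'   subtype A vs subtype B), each of size >= 2.
#' @param n_permutations Number of label permutations for the empirical null.
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive_if_possible If `TRUE` and the number of distinct label
#'   assignments is at most `n_permutations`, enumerate all assignments
#'   exactly once instead of sampling.
#' @return A `ComparisonSpec`.
#' @export
comparison_spec <- function(group_a, group_b, n_permutations = 1000,
                            seed = 1L, exhaustive_if_possible = FALSE) {
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  structure(list(group_a = group_a, group_b = group_b,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 exhaustive_if_possible = isTRUE(exhaustive_if_possible)),
            class = "ComparisonSpec")
}

#' Treated-vs-control comparison spec for one cell type
#'
#' Convenience constructor reading the generator's metadata columns.
#'
#' @param x An `OmicsMatrix` with `cell_type` and `condition` metadata.
#' @param cell_type Cell type to compare.
#' @param ... Passed to [comparison_spec()].
#' @export
cell_type_spec <- function(x, cell_type, ...) {
  m <- x$metadata
  sel <- m$cell_type == cell_type
  comparison_spec(group_a = m$sample_id[sel & m$condition == "treated"],
                  group_b = m$sample_id[sel & m$condition == "control"], ...)
}

# Vectorized per-feature Welch statistics for one column split.
welch_stats <- function(values, ia, ib) {
  na <- length(ia)
  nb <- length(ib)
  xa <- values[, ia, drop = FALSE]
  xb <- values[, ib, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  lfc <- ma - mb
  se <- sqrt(va / na + vb / nb)
  t <- lfc / se
  deg <- se == 0
  if (any(deg)) t[deg] <- ifelse(lfc[deg] == 0, 0, sign(lfc[deg]) * T_SENTINEL)
  list(mean_a = ma, mean_b = mb, log2fc = lfc, t = t)
}

#' Observed per-feature statistics for a comparison
#'
#' `log2fc` is the difference of group means on the log scale
#' (group_a - group_b); `t` is the Welch (unequal-variance) two-sample
#' statistic. Features with zero variance in both groups get `t = 0` when the
#' means are equal and a signed large sentinel otherwise.
#'
#' @param x An `OmicsMatrix` with layer `"lognorm"` or `"protein"`.
#' @param spec A [comparison_spec()].
#' @return Data frame: `feature_id`, `mean_a`, `mean_b`, `log2fc`, `t`.
#' @export
observed_stats <- function(x, spec) {
  stopifnot(inherits(x, "OmicsMatrix"), inherits(spec, "ComparisonSpec"))
  if (x$layer == "fpkm") {
    stop("observed_stats expects a log-scale layer (lognorm or protein)",
         call. = FALSE)
  }
  miss <- setdiff(c(spec$group_a, spec$group_b), colnames(x$values))
  if (length(miss) > 0) {
    stop("samples not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  w <- welch_stats(x$values, match(spec$group_a, colnames(x$values)),
                   match(spec$group_b, colnames(x$values)))
  data.frame(feature_id = rownames(x$values), mean_a = w$mean_a,
             mean_b = w$mean_b, log2fc = w$log2fc, t = w$t,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the pooled permutation null distribution
#'
#' Sample labels are shuffled across the union of both groups, preserving
#' group sizes; the Welch t and log2FC are recomputed per feature and pooled
#' across features and permutations. In exhaustive mode all distinct label
#' assignments (choose(n, n_a)) are enumerated exactly once; otherwise
#' assignments are sampled uniformly with replacement, since for small
#' designs 1000 random permutations necessarily repeat assignments.
#'
#' @param x An `OmicsMatrix` (log-scale layer).
#' @param spec A [comparison_spec()].
#' @return A `NullDistribution`: pooled `t` and `log2fc` vectors plus the
#'   permutation ledger (`n_permutations`, `exhaustive`, `seed`,
#'   `n_features`).
#' @export
build_null <- function(x, spec) {
  stopifnot(inherits(x, "OmicsMatrix"), inherits(spec, "ComparisonSpec"))
  cols <- colnames(x$values)
  union_idx <- match(c(spec$group_a, spec$group_b), cols)
  n_tot <- length(union_idx)
  na <- length(spec$group_a)
  n_distinct <- choose(n_tot, na)
  exhaustive <- spec$exhaustive_if_possible && n_distinct <= spec$n_permutations
  if (exhaustive) {
    assign_a <- utils::combn(n_tot, na)
  } else {
    set.seed(spec$seed)
    assign_a <- replicate(spec$n_permutations, sample.int(n_tot, na))
  }
  B <- ncol(assign_a)
  nf <- nrow(x$values)
  t_null <- matrix(0, nf, B)
  lfc_null <- matrix(0, nf, B)
  for (b in seq_len(B)) {
    ia <- union_idx[assign_a[, b]]
    ib <- union_idx[-assign_a[, b]]
    w <- welch_stats(x$values, ia, ib)
    t_null[, b] <- w$t
    lfc_null[, b] <- w$log2fc
  }
  structure(list(t = as.vector(t_null), log2fc = as.vector(lfc_null),
                 n_permutations = B, exhaustive = exhaustive,
                 seed = spec$seed, n_features = nf),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution: %d pooled values (%d features x %d %s), seed %d\n",
              length(x$t), x$n_features, x$n_permutations,
              if (x$exhaustive) "exhaustive assignments" else "sampled permutations",
              x$seed))
  invisible(x)
}

#' Empirical p-values against a pooled null
#'
#' Two-sided: `p = (1 + #[|t_null| >= |t_obs|]) / (1 + N_null)`, ranked
#' against the null pooled across all features (the pooling is what makes
#' the p-value "adjusted"), with an add-one correction so p is never 0.
#'
#' @param stats Data frame from [observed_stats()].
#' @param null A `NullDistribution`.
#' @return `stats` with a `p_empirical` column appended.
#' @export
empirical_pvalues <- function(stats, null) {
  stopifnot(inherits(null, "NullDistribution"))
  if (length(null$t) == 0) stop("empty null distribution", call. = FALSE)
  sorted <- sort(abs(null$t))
  N <- length(sorted)
  x <- abs(stats$t)
  # relative epsilon so null values tied with the observed statistic (same
  # split recomputed in a different summation order) count as >=
  x_adj <- x * (1 - 1e-9) - 1e-12
  cnt <- N - findInterval(x_adj, sorted, left.open = TRUE)
  stats$p_empirical <- (1 + cnt) / (1 + N)
  stats
}

#' Derive a fold-change cutoff from the null log2FC distribution
#'
#' The cutoff is the mean of the magnitudes of the lower and upper
#' percentiles of the pooled null log2FC distribution,
#' `(|q_lower| + |q_upper|) / 2` with linear-interpolation percentiles.
#'
#' @param null A `NullDistribution` or a numeric vector of null log2FCs.
#' @param lower_pct,upper_pct Percentiles (0-100 scale), default 2.5 / 97.5.
#' @return A positive fold-change cutoff.
#' @export
derive_fc_cutoff <- function(null, lower_pct = 2.5, upper_pct = 97.5) {
  v <- if (inherits(null, "NullDistribution")) null$log2fc else null
  if (length(v) == 0) stop("empty null distribution", call. = FALSE)
  (abs(percentile(v, lower_pct)) + abs(percentile(v, upper_pct))) / 2
}

#' Range-separation gap between two replicate groups
#'
#' `min(H) - max(L)` where `H` is the group with the higher mean and `L` the
#' other; ties take `group_a` as `H`. Positive only when the replicate ranges
#' separate completely; negative when they overlap.
#'
#' @param a,b Non-empty numeric vectors (group_a, group_b).
#' @return The gap (real, possibly negative).
#' @export
compute_gap <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (mean(a) >= mean(b)) min(a) - max(b) else min(b) - max(a)
}

# Per-feature gaps for a comparison, vectorized over the matrix rows.
matrix_gaps <- function(x, spec) {
  ia <- match(spec$group_a, colnames(x$values))
  ib <- match(spec$group_b, colnames(x$values))
  xa <- x$values[, ia, drop = FALSE]
  xb <- x$values[, ib, drop = FALSE]
  a_high <- rowMeans(xa) >= rowMeans(xb)
  gap_a <- apply(xa, 1, min) - apply(xb, 1, max)
  gap_b <- apply(xb, 1, min) - apply(xa, 1, max)
  ifelse(a_high, gap_a, gap_b)
}

#' Derive the gap cutoff from stage-1 selected features
#'
#' Mean of the 25th and 75th linear-interpolation percentiles of the gap
#' distribution over the initially selected features.
#'
#' @param gaps Numeric vector of gap statistics (stage-1 features only).
#' @return The gap cutoff.
#' @export
derive_gap_cutoff <- function(gaps) {
  if (length(gaps) == 0) stop("empty gap vector", call. = FALSE)
  (percentile(gaps, 25) + percentile(gaps, 75)) / 2
}

#' Cutoff set for differential calling
#'
#' @param p_cutoff Empirical p threshold (strict <).
#' @param fc_cutoff Absolute log2FC threshold (strict >).
#' @param fc_mode `"fixed"` or `"null_percentile"`.
#' @param gap_cutoff Gap threshold, or `NA` when no gap stage is used.
#' @param gap_mode `"none"` or `"quartile_mean"`.
#' @param provenance Named list recording how derived cutoffs were obtained
#'   (percentiles, seed, null size).
#' @return A `CutoffSet`.
#' @export
cutoff_set <- function(p_cutoff, fc_cutoff, fc_mode = c("fixed", "null_percentile"),
                       gap_cutoff = NA_real_, gap_mode = c("none", "quartile_mean"),
                       provenance = list()) {
  fc_mode <- match.arg(fc_mode)
  gap_mode <- match.arg(gap_mode)
  if (!is.na(fc_cutoff) && fc_cutoff <= 0) {
    stop("fc_cutoff must be positive", call. = FALSE)
  }
  structure(list(p_cutoff = p_cutoff, fc_cutoff = fc_cutoff, fc_mode = fc_mode,
                 gap_cutoff = gap_cutoff, gap_mode = gap_mode,
                 provenance = provenance),
            class = "CutoffSet")
}

#' Apply calling thresholds to per-feature statistics
#'
#' Stage 1 keeps features with `p_empirical < p_cutoff` and
#' `|log2FC| > fc_cutoff` (both strict). When `gap_mode = "quartile_mean"`,
#' stage 2 additionally requires the gap statistic to exceed `gap_cutoff`;
#' by default the absolute gap `|gap|` is compared (`gap_signed = TRUE`
#' compares the signed gap, i.e. requires positive range separation).
#' Calls are `"up"` / `"down"` by the sign of log2FC, `"ns"` otherwise.
#'
#' @param stats Data frame with `p_empirical`, `log2fc` and (for gap calling)
#'   `gap` columns.
#' @param cutoffs A [cutoff_set()].
#' @param gap_signed Compare the signed gap instead of `|gap|`.
#' @return `stats` with a `call` column.
#' @export
call_features <- function(stats, cutoffs, gap_signed = FALSE) {
  stopifnot(inherits(cutoffs, "CutoffSet"))
  keep <- stats$p_empirical < cutoffs$p_cutoff &
    abs(stats$log2fc) > cutoffs$fc_cutoff
  if (cutoffs$gap_mode == "quartile_mean") {
    if (is.null(stats$gap)) stop("gap column required for gap calling", call. = FALSE)
    if (is.na(cutoffs$gap_cutoff)) stop("gap_cutoff not set", call. = FALSE)
    g <- if (gap_signed) stats$gap else abs(stats$gap)
    keep <- keep & g > cutoffs$gap_cutoff
  }
  stats$call <- ifelse(keep, ifelse(stats$log2fc > 0, "up", "down"), "ns")
  stats
}

#' Run a full two-group differential comparison
#'
#' Orchestrates observed statistics, the pooled permutation null, empirical
#' p-values, cutoff derivation and calling under one of three presets:
#' \describe{
#'   \item{deg}{transcripts: fixed cutoffs p < 0.05, |log2FC| > 0.58.}
#'   \item{dep}{proteins: p < 0.2, null-percentile fold-change cutoff
#'     (mean of |2.5th| and |97.5th| null log2FC percentiles), then a
#'     quartile-mean gap filter derived from the stage-1 features.}
#'   \item{cohort}{large two-group designs: p < 0.05, null-percentile
#'     fold-change cutoff, no gap stage.}
#' }
#' A Benjamini-Hochberg column `p_bh` is emitted alongside the pooled
#' empirical p for inspection; calling uses `p_empirical`.
#'
#' @param x An `OmicsMatrix`; layer `"lognorm"` for deg/cohort, `"protein"`
#'   for dep.
#' @param spec A [comparison_spec()].
#' @param preset `"deg"`, `"dep"` or `"cohort"`.
#' @param p_cutoff,fc_cutoff Optional overrides of the preset thresholds
#'   (`fc_cutoff` forces fixed mode).
#' @param gap_signed Use the signed gap in stage 2 (dep preset).
#' @return A list with `stats` (calls set), `cutoffs` (provenance included)
#'   and `null` (the `NullDistribution`).
#' @export
run_comparison <- function(x, spec, preset = c("deg", "dep", "cohort"),
                           p_cutoff = NULL, fc_cutoff = NULL,
                           gap_signed = FALSE) {
  preset <- match.arg(preset)
  want_layer <- switch(preset, deg = "lognorm", cohort = "lognorm", dep = "protein")
  if (x$layer != want_layer) {
    stop(sprintf("preset '%s' expects layer '%s', got '%s'",
                 preset, want_layer, x$layer), call. = FALSE)
  }
  stats <- observed_stats(x, spec)
  null <- build_null(x, spec)
  stats <- empirical_pvalues(stats, null)
  stats$p_bh <- stats::p.adjust(stats$p_empirical, method = "BH")

  p_def <- switch(preset, deg = 0.05, dep = 0.2, cohort = 0.05)
  p_use <- if (is.null(p_cutoff)) p_def else p_cutoff
  prov <- list(preset = preset, seed = spec$seed,
               n_null = length(null$t), exhaustive = null$exhaustive,
               percentile_rule = "linear interpolation (type 7)")
  if (is.null(fc_cutoff) && preset != "deg") {
    fc_use <- derive_fc_cutoff(null)
    fc_mode <- "null_percentile"
    prov$fc_percentiles <- c(2.5, 97.5)
  } else {
    fc_use <- if (is.null(fc_cutoff)) 0.58 else fc_cutoff
    fc_mode <- "fixed"
  }

  if (preset == "dep") {
    stats$gap <- matrix_gaps(x, spec)
    stage1 <- stats$p_empirical < p_use & abs(stats$log2fc) > fc_use
    if (!any(stage1)) {
      gap_cut <- Inf  # no stage-1 features: nothing can be called
    } else {
      g <- if (gap_signed) stats$gap[stage1] else abs(stats$gap[stage1])
      gap_cut <- derive_gap_cutoff(g)
    }
    prov$gap_percentiles <- c(25, 75)
    cuts <- cutoff_set(p_use, fc_use, fc_mode, gap_cutoff = gap_cut,
                       gap_mode = "quartile_mean", provenance = prov)
  } else {
    cuts <- cutoff_set(p_use, fc_use, fc_mode, provenance = prov)
  }
  stats <- call_features(stats, cuts, gap_signed = gap_signed)
  list(stats = stats, cutoffs = cuts, null = null)
}
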