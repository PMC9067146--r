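#' Simulation design for synthetic omics data
#'
#' Describes the experimental design and effect structure the generators
#' emulate: several cell types, each measured in control and treated
#' conditions with a few replicates, with a fraction of features planted as
#' up- or downregulated at a fixed log2 effect size and log-normal replicate
#' noise.
#'
#' @param n_features Number of features (genes / proteins).
#' @param n_cell_types Number of cell types (strata); each gets its own
#'   two-group comparison.
#' @param replicates_per_group Replicates per (cell type, condition).
#' @param frac_up,frac_down Fractions of features planted up / down per cell
#'   type; `frac_up + frac_down <= 1`.
#' @param effect_log2fc Planted |log2 fold change| on the log2 scale.
#' @param noise_sd Replicate noise sd on the log2 scale (>= 0).
#' @param baseline_log_mean,baseline_log_sd Mean and sd of the per-feature
#'   baseline on the log2 abundance scale.
#' @param frac_expressed Fraction of features kept above the expressed filter;
#'   the rest are forced below FPKM 1 in every sample.
#' @param seed Integer seed; one global seed fans out to fixed per-generator
#'   substreams so adding a generator does not perturb existing fixtures.
#' @return A `SimDesign` list.
#' @export
sim_design <- function(n_features = 2000, n_cell_types = 3,
                       replicates_per_group = 3,
                       frac_up = 0.05, frac_down = 0.05,
                       effect_log2fc = 1.0, noise_sd = 0.25,
                       baseline_log_mean = 3, baseline_log_sd = 1.5,
                       frac_expressed = 0.8, seed = 1L) {
  d <- list(n_features = as.integer(n_features),
            n_cell_types = as.integer(n_cell_types),
            replicates_per_group = as.integer(replicates_per_group),
            frac_up = frac_up, frac_down = frac_down,
            effect_log2fc = effect_log2fc, noise_sd = noise_sd,
            baseline_log_mean = baseline_log_mean,
            baseline_log_sd = baseline_log_sd,
            frac_expressed = frac_expressed, seed = as.integer(seed))
  if (d$n_features < 1 || d$n_cell_types < 1 || d$replicates_per_group < 1) {
    stop("invalid design: all counts must be >= 1", call. = FALSE)
  }
  if (d$frac_up < 0 || d$frac_down < 0 || d$frac_up + d$frac_down > 1) {
    stop("invalid design: frac_up + frac_down must lie in [0, 1]", call. = FALSE)
  }
  if (d$noise_sd < 0 || d$effect_log2fc < 0) {
    stop("invalid design: noise_sd and effect_log2fc must be non-negative",
         call. = FALSE)
  }
  if (d$baseline_log_sd <= 0) {
    stop("invalid design: baseline_log_sd must be positive", call. = FALSE)
  }
  if (d$frac_expressed < 0 || d$frac_expressed > 1) {
    stop("invalid design: frac_expressed must lie in [0, 1]", call. = FALSE)
  }
  class(d) <- "SimDesign"
  d
}

#' Canonical synthetic feature and cell-type ids
#'
#' All generators draw feature ids from the same universe, so expression,
#' protein, annotation and cohort fixtures can be integrated.
#'
#' @param n Number of ids.
#' @return Character vector of ids.
#' @export
feature_ids <- function(n) sprintf("f%05d", seq_len(n))

#' @rdname feature_ids
#' @export
cell_type_names <- function(n) sprintf("CT%d", seq_len(n))

# Plant per-cell-type up/down feature sets among candidate (expressed) rows.
plant_truth <- function(design, candidates) {
  n_up <- round(design$frac_up * design$n_features)
  n_down <- round(design$frac_down * design$n_features)
  ids <- feature_ids(design$n_features)
  cts <- cell_type_names(design$n_cell_types)
  truth <- vector("list", design$n_cell_types)
  planted <- vector("list", design$n_cell_types)
  for (i in seq_along(cts)) {
    sel <- sample(candidates, n_up + n_down)
    up <- sel[seq_len(n_up)]
    down <- sel[n_up + seq_len(n_down)]
    dir <- rep("null", design$n_features)
    dir[up] <- "up"
    dir[down] <- "down"
    lfc <- rep(0, design$n_features)
    lfc[up] <- design$effect_log2fc
    lfc[down] <- -design$effect_log2fc
    truth[[i]] <- data.frame(feature_id = ids, cell_type = cts[i],
                             direction = dir, planted_log2fc = lfc,
                             stringsAsFactors = FALSE)
    planted[[i]] <- list(up = up, down = down)
  }
  list(table = do.call(rbind, truth), planted = planted)
}

#' Generate a synthetic FPKM expression matrix with planted effects
#'
#' Each expressed feature gets a log-normal baseline; treated samples are
#' shifted by the planted log2 fold change and every sample receives normal
#' noise on the log2(FPKM+1) scale, so planted effects are exact on the scale
#' the downstream analysis uses. Non-expressed features are forced below
#' FPKM 1 in all samples.
#'
#' @param design A [sim_design()].
#' @return A list with `matrix` (an `OmicsMatrix`, layer `"fpkm"`) and
#'   `truth` (one row per feature x cell type: planted direction and log2FC).
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "SimDesign"))
  set.seed(design$seed + 1L)
  n <- design$n_features
  ids <- feature_ids(n)
  cts <- cell_type_names(design$n_cell_types)
  reps <- design$replicates_per_group

  n_expr <- round(design$frac_expressed * n)
  expressed <- sort(sample.int(n, n_expr))
  # keep expressed baselines high enough that replicate noise and a planted
  # downregulation cannot push any sample below the FPKM >= 1 filter
  floor_log2 <- 1 + design$effect_log2fc + 4 * design$noise_sd
  baseline <- stats::rnorm(n, design$baseline_log_mean, design$baseline_log_sd)
  baseline <- pmax(baseline, floor_log2)

  pt <- plant_truth(design, expressed)

  n_samp <- design$n_cell_types * 2L * reps
  values <- matrix(0, n, n_samp)
  meta <- vector("list", n_samp)
  col <- 0L
  for (i in seq_along(cts)) {
    lfc <- pt$table$planted_log2fc[pt$table$cell_type == cts[i]]
    for (cond in c("control", "treated")) {
      shift <- if (cond == "treated") lfc else 0
      for (r in seq_len(reps)) {
        col <- col + 1L
        x <- baseline + shift + stats::rnorm(n, 0, design$noise_sd)
        fpkm <- 2^x - 1
        fpkm[-expressed] <- stats::runif(n - n_expr, 0, 0.5)
        values[, col] <- pmax(fpkm, 0)
        meta[[col]] <- data.frame(sample_id = sprintf("%s_%s_r%d", cts[i], cond, r),
                                  cell_type = cts[i], condition = cond,
                                  replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta)
  rownames(values) <- ids
  colnames(values) <- meta$sample_id
  list(matrix = omics_matrix(values, meta, layer = "fpkm"), truth = pt$table)
}

#' Generate a synthetic normalized protein-abundance matrix
#'
#' Produces continuous log-abundance values with the same design shape as the
#' expression generator. A `coupling` fraction of the planted effects is
#' shared with a paired expression truth table (same features, same
#' directions); the remainder is planted independently. Protein effect and
#' noise default to scaled-down versions of the design values so the derived
#' per-cell-line fold-change cutoffs land in a realistic TMT range.
#'
#' @param design A [sim_design()].
#' @param coupling Fraction in `[0, 1]` of planted protein effects shared
#'   with `expr_truth`.
#' @param expr_truth Truth table from [generate_expression()] to couple to,
#'   or `NULL` for fully independent planting.
#' @param effect_scale,noise_scale Multipliers applied to the design's
#'   `effect_log2fc` and `noise_sd` for the protein layer.
#' @return A list with `matrix` (layer `"protein"`) and `truth`.
#' @export
generate_proteome <- function(design, coupling = 0.5, expr_truth = NULL,
                              effect_scale = 0.6, noise_scale = 0.7) {
  stopifnot(inherits(design, "SimDesign"))
  if (coupling < 0 || coupling > 1) {
    stop("`coupling` must lie in [0, 1]", call. = FALSE)
  }
  set.seed(design$seed + 2L)
  n <- design$n_features
  ids <- feature_ids(n)
  cts <- cell_type_names(design$n_cell_types)
  reps <- design$replicates_per_group
  effect <- design$effect_log2fc * effect_scale
  noise <- design$noise_sd * noise_scale
  n_up <- round(design$frac_up * n)
  n_down <- round(design$frac_down * n)

  baseline <- stats::rnorm(n, 0, 1)

  truth <- vector("list", design$n_cell_types)
  n_samp <- design$n_cell_types * 2L * reps
  values <- matrix(0, n, n_samp)
  meta <- vector("list", n_samp)
  col <- 0L
  for (i in seq_along(cts)) {
    if (!is.null(expr_truth)) {
      et <- expr_truth[expr_truth$cell_type == cts[i], ]
      expr_up <- which(et$direction == "up")
      expr_down <- which(et$direction == "down")
      n_share_up <- min(round(coupling * n_up), length(expr_up))
      n_share_down <- min(round(coupling * n_down), length(expr_down))
      up <- if (n_share_up > 0) sample(expr_up, n_share_up) else integer(0)
      down <- if (n_share_down > 0) sample(expr_down, n_share_down) else integer(0)
      free <- setdiff(seq_len(n), c(expr_up, expr_down))
      extra <- sample(free, (n_up - n_share_up) + (n_down - n_share_down))
      up <- c(up, extra[seq_len(n_up - n_share_up)])
      down <- c(down, extra[(n_up - n_share_up) + seq_len(n_down - n_share_down)])
    } else {
      sel <- sample.int(n, n_up + n_down)
      up <- sel[seq_len(n_up)]
      down <- sel[n_up + seq_len(n_down)]
    }
    dir <- rep("null", n)
    dir[up] <- "up"
    dir[down] <- "down"
    lfc <- rep(0, n)
    lfc[up] <- effect
    lfc[down] <- -effect
    truth[[i]] <- data.frame(feature_id = ids, cell_type = cts[i],
                             direction = dir, planted_log2fc = lfc,
                             stringsAsFactors = FALSE)
    for (cond in c("control", "treated")) {
      shift <- if (cond == "treated") lfc else 0
      for (r in seq_len(reps)) {
        col <- col + 1L
        values[, col] <- baseline + shift + stats::rnorm(n, 0, noise)
        meta[[col]] <- data.frame(sample_id = sprintf("%s_%s_r%d", cts[i], cond, r),
                                  cell_type = cts[i], condition = cond,
                                  replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta)
  rownames(values) <- ids
  colnames(values) <- meta$sample_id
  list(matrix = omics_matrix(values, meta, layer = "protein"),
       truth = do.call(rbind, truth))
}

#' Gene-set collection (GMT-backed)
#'
#' @param terms Data frame with columns `term_id`, `name`, `level`, `module`.
#' @param members Named list (by `term_id`) of character member vectors.
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(terms, members) {
  stopifnot(is.data.frame(terms),
            all(c("term_id", "name", "level", "module") %in% names(terms)))
  if (anyDuplicated(terms$term_id)) stop("duplicate term ids", call. = FALSE)
  members <- members[terms$term_id]
  if (any(lengths(members) == 0)) stop("empty member sets", call. = FALSE)
  structure(list(terms = terms, members = members), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d terms, %d modules, member sizes %d-%d\n",
              nrow(x$terms), length(unique(x$terms$module)),
              min(lengths(x$members)), max(lengths(x$members))))
  invisible(x)
}

default_modules <- c("metabolism", "cell_proliferation",
                     "cell_development", "immune_response")

#' Generate a synthetic gene-set annotation
#'
#' Terms get member sets sampled from the gene universe, a level in 2-4 and a
#' level-1 module label cycling over `n_modules` modules. Every term is
#' guaranteed to share at least 3 members with another term of its module
#' (terms within a module are chained), so similarity edges are reachable by
#' construction.
#'
#' @param n_terms Number of terms.
#' @param size_range Length-2 integer range of member-set sizes (min >= 3).
#' @param n_genes Size of the gene universe (ids match the matrix generators).
#' @param n_modules Number of level-1 modules (defaults to the four
#'   process-level groups: metabolism, cell proliferation, cell development,
#'   immune response).
#' @param seed Integer seed.
#' @return A `GeneSetCollection`.
#' @export
generate_annotation <- function(n_terms = 50, size_range = c(10, 40),
                                n_genes = 2000, n_modules = 4, seed = 1L) {
  if (length(size_range) != 2 || size_range[1] < 3) {
    stop("size_range minimum must be >= 3", call. = FALSE)
  }
  if (size_range[2] > n_genes) {
    stop("size_range exceeds the gene universe", call. = FALSE)
  }
  if (n_modules < 1) stop("n_modules must be >= 1", call. = FALSE)
  set.seed(seed + 3L)
  universe <- feature_ids(n_genes)
  modules <- if (n_modules <= length(default_modules)) {
    default_modules[seq_len(n_modules)]
  } else {
    sprintf("module%02d", seq_len(n_modules))
  }
  term_ids <- sprintf("T%04d", seq_len(n_terms))
  module_of <- modules[((seq_len(n_terms) - 1L) %% n_modules) + 1L]
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
  members <- vector("list", n_terms)
  names(members) <- term_ids
  prev_in_module <- stats::setNames(rep(NA_integer_, n_modules), modules)
  for (i in seq_len(n_terms)) {
    mem <- sample(universe, sizes[i])
    prev <- prev_in_module[[module_of[i]]]
    if (!is.na(prev)) {
      # chain: share >= 3 members with the previous term of the same module
      shared <- sample(members[[prev]], 3)
      mem <- unique(c(shared, setdiff(mem, shared)))[seq_len(sizes[i])]
    }
    members[[i]] <- mem
    prev_in_module[[module_of[i]]] <- i
  }
  terms <- data.frame(term_id = term_ids,
                      name = sprintf("process %s", tolower(term_ids)),
                      level = sample(2:4, n_terms, replace = TRUE),
                      module = module_of, stringsAsFactors = FALSE)
  gene_set_collection(terms, members)
}

#' Generate a synthetic two-group cohort expression matrix
#'
#' Emulates a large unbalanced tumour-subtype comparison (e.g. 115 vs 535
#' samples) at configurable, smaller default sizes. Group A carries the
#' planted subtype effects relative to group B.
#'
#' @param n_group_a,n_group_b Group sizes (each >= 2).
#' @param n_features Number of features.
#' @param frac_up,frac_down Planted fractions (up/down in group A vs B).
#' @param effect_log2fc Planted |log2FC|.
#' @param noise_sd Per-sample noise sd on the log2 scale.
#' @param baseline_log_mean,baseline_log_sd Baseline distribution.
#' @param frac_expressed Fraction of features above the expressed filter.
#' @param seed Integer seed.
#' @return A list with `matrix` (layer `"fpkm"`, metadata column `group` with
#'   levels `"A"`/`"B"`) and `truth` (cell_type `"cohort"`).
#' @export
generate_cohort <- function(n_group_a = 20, n_group_b = 80, n_features = 2000,
                            frac_up = 0.05, frac_down = 0.05,
                            effect_log2fc = 0.5, noise_sd = 0.5,
                            baseline_log_mean = 3, baseline_log_sd = 1.5,
                            frac_expressed = 0.8, seed = 1L) {
  if (n_group_a < 2 || n_group_b < 2) {
    stop("both group sizes must be >= 2", call. = FALSE)
  }
  design <- sim_design(n_features = n_features, n_cell_types = 1,
                       replicates_per_group = 2, frac_up = frac_up,
                       frac_down = frac_down, effect_log2fc = effect_log2fc,
                       noise_sd = noise_sd, baseline_log_mean = baseline_log_mean,
                       baseline_log_sd = baseline_log_sd,
                       frac_expressed = frac_expressed, seed = seed)
  set.seed(design$seed + 4L)
  n <- design$n_features
  ids <- feature_ids(n)
  n_expr <- round(frac_expressed * n)
  expressed <- sort(sample.int(n, n_expr))
  floor_log2 <- 1 + effect_log2fc + 4 * noise_sd
  baseline <- pmax(stats::rnorm(n, baseline_log_mean, baseline_log_sd), floor_log2)

  pt <- plant_truth(design, expressed)
  truth <- pt$table
  truth$cell_type <- "cohort"
  lfc <- truth$planted_log2fc

  n_samp <- n_group_a + n_group_b
  grp <- rep(c("A", "B"), c(n_group_a, n_group_b))
  values <- matrix(0, n, n_samp)
  for (j in seq_len(n_samp)) {
    shift <- if (grp[j] == "A") lfc else 0
    x <- baseline + shift + stats::rnorm(n, 0, noise_sd)
    fpkm <- 2^x - 1
    fpkm[-expressed] <- stats::runif(n - n_expr, 0, 0.5)
    values[, j] <- pmax(fpkm, 0)
  }
  meta <- data.frame(sample_id = sprintf("S%03d_%s", seq_len(n_samp), grp),
                     group = grp, stringsAsFactors = FALSE)
  rownames(values) <- ids
  colnames(values) <- meta$sample_id
  list(matrix = omics_matrix(values, meta, layer = "fpkm"), truth = truth)
}

#' Write a truth table as TSV
#' @param truth Truth table data frame.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
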