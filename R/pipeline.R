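#' Default pipeline configuration
#'
#' Parameter defaults mirror the study design the synthetic generators
#' emulate: 3 cell types x {control, treated} x 3 replicates, 1000
#' permutations, DEG thresholds p < 0.05 and |log2FC| > 0.58, DEP thresholds
#' p < 0.2 with null-percentile fold-change and quartile-mean gap cutoffs,
#' enrichment at EASE p < 0.05, term networks at >= 3 shared members and a
#' 95th-percentile Dice cutoff.
#'
#' @param seed Global seed; fans out to the generator substreams.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(n_features = 2000, n_cell_types = 3, replicates_per_group = 3,
                  frac_up = 0.05, frac_down = 0.05, effect_log2fc = 1.0,
                  noise_sd = 0.25, frac_expressed = 0.8),
    proteome = list(coupling = 0.5, effect_scale = 0.6, noise_scale = 0.7),
    annotation = list(n_terms = 60, size_range = c(10, 40), n_modules = 4),
    cohort = list(n_group_a = 20, n_group_b = 80, effect_log2fc = 0.5,
                  noise_sd = 0.5),
    n_permutations = 1000,
    deg = list(p_cutoff = 0.05, fc_cutoff = 0.58),
    dep = list(p_cutoff = 0.2),
    cohort_call = list(p_cutoff = 0.05),
    enrich = list(p_cutoff = 0.05),
    network = list(min_shared = 3, dice_pct = 95, dice_universe = "list"),
    integrate = list(decimals = 1, colour_rule = "absmax")
  )
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a config file requires the yaml package", call. = FALSE)
    }
    user <- yaml::read_yaml(config)
    base <- default_config(seed = if (!is.null(user$seed)) user$seed else 1L)
    config <- utils::modifyList(base, user)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full synthetic multi-omics pipeline
#'
#' Executes the stages in dependency order — simulate, normalize,
#' differential calling (per cell type for transcripts and proteins, plus the
#' two-group cohort), enrichment, term-network construction, and cross-omics
#' integration — writing every result table under `out_dir` together with a
#' manifest recording seeds, derived cutoffs and row counts. Re-running an
#' identical configuration reproduces byte-identical tables.
#'
#' @param config Configuration list from [default_config()], or the path of
#'   a YAML file overriding its entries.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results: `deg_results`,
#'   `dep_results`, `cohort_result`, `enrichment`, `networks`, `venn`,
#'   `overlaps`, `pathway`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("permomics_")) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("seed\t%d", config$seed),
                sprintf("n_permutations\t%d", config$n_permutations))

  ## simulate
  design <- do.call(sim_design, c(config$design, list(seed = config$seed)))
  expr <- generate_expression(design)
  prot <- do.call(generate_proteome,
                  c(list(design = design, expr_truth = expr$truth),
                    config$proteome))
  ann <- do.call(generate_annotation,
                 c(config$annotation,
                   list(n_genes = design$n_features, seed = config$seed)))
  coh <- do.call(generate_cohort,
                 c(config$cohort, list(n_features = design$n_features,
                                       seed = config$seed)))
  write_omics(expr$matrix, file.path(out_dir, "expression_fpkm.tsv"))
  write_omics(prot$matrix, file.path(out_dir, "protein_abundance.tsv"))
  write_gmt(ann, file.path(out_dir, "annotation.gmt"))
  write_truth(expr$truth, file.path(out_dir, "expression_truth.tsv"))
  write_truth(prot$truth, file.path(out_dir, "protein_truth.tsv"))

  cts <- cell_type_names(design$n_cell_types)

  ## normalize + differential, per cell type
  deg_results <- list()
  dep_results <- list()
  backgrounds <- list()
  for (ct in cts) {
    samples <- expr$matrix$metadata$sample_id[expr$matrix$metadata$cell_type == ct]
    sub <- subset_omics(expr$matrix, samples = samples)
    norm <- quantile_normalize(log_transform(filter_expressed(sub, "all_min")))
    spec <- cell_type_spec(norm, ct, n_permutations = config$n_permutations,
                           seed = config$seed)
    res <- run_comparison(norm, spec, preset = "deg",
                          p_cutoff = config$deg$p_cutoff,
                          fc_cutoff = config$deg$fc_cutoff)
    deg_results[[ct]] <- res$stats
    backgrounds[[ct]] <- res$stats$feature_id
    utils::write.table(res$stats, file.path(out_dir, sprintf("deg_%s.tsv", ct)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    psub <- subset_omics(prot$matrix,
                         samples = prot$matrix$metadata$sample_id[
                           prot$matrix$metadata$cell_type == ct])
    pspec <- cell_type_spec(psub, ct, n_permutations = config$n_permutations,
                            seed = config$seed)
    pres <- run_comparison(psub, pspec, preset = "dep",
                           p_cutoff = config$dep$p_cutoff)
    dep_results[[ct]] <- pres$stats
    utils::write.table(pres$stats, file.path(out_dir, sprintf("dep_%s.tsv", ct)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest,
                  sprintf("%s\tdeg_called\t%d", ct, sum(res$stats$call != "ns")),
                  sprintf("%s\tdep_fc_cutoff\t%.6g", ct, pres$cutoffs$fc_cutoff),
                  sprintf("%s\tdep_gap_cutoff\t%.6g", ct, pres$cutoffs$gap_cutoff),
                  sprintf("%s\tdep_called\t%d", ct, sum(pres$stats$call != "ns")))
  }

  ## cohort comparison
  cmeta <- coh$matrix$metadata
  cnorm <- quantile_normalize(log_transform(filter_expressed(coh$matrix, "majority")))
  cspec <- comparison_spec(cmeta$sample_id[cmeta$group == "A"],
                           cmeta$sample_id[cmeta$group == "B"],
                           n_permutations = config$n_permutations,
                           seed = config$seed)
  cres <- run_comparison(cnorm, cspec, preset = "cohort",
                         p_cutoff = config$cohort_call$p_cutoff)
  utils::write.table(cres$stats, file.path(out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(manifest,
                sprintf("cohort\tfc_cutoff\t%.6g", cres$cutoffs$fc_cutoff),
                sprintf("cohort\tcalled\t%d", sum(cres$stats$call != "ns")))

  ## union call sets across cell types
  deg_sets <- call_sets(deg_results)
  dep_sets <- call_sets(dep_results)
  up_genes <- sort(unique(unlist(lapply(deg_sets$sets, `[[`, "up"))))
  down_genes <- sort(unique(unlist(lapply(deg_sets$sets, `[[`, "down"))))
  up_prot <- sort(unique(unlist(lapply(dep_sets$sets, `[[`, "up"))))
  down_prot <- sort(unique(unlist(lapply(dep_sets$sets, `[[`, "down"))))

  ## enrichment (background = expressed union across cell types)
  background <- sort(unique(unlist(backgrounds)))
  enr <- enrich_lists(up_genes, down_genes, ann, background,
                      p_cutoff = config$enrich$p_cutoff)
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  shares <- categorize_level1(enr, decimals = config$integrate$decimals)
  utils::write.table(shares, file.path(out_dir, "module_shares.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## term networks per direction
  networks <- list()
  for (dir in c("up", "down")) {
    lst <- if (dir == "up") up_genes else down_genes
    tg <- build_term_graph(enr, ann, dir, feature_list = lst,
                           min_shared = config$network$min_shared,
                           pct = config$network$dice_pct,
                           dice_universe = config$network$dice_universe)
    tg <- cluster_and_group(tg)
    write_term_graph(tg,
                     graphml = file.path(out_dir, sprintf("termnet_%s.graphml", dir)),
                     edges_tsv = file.path(out_dir, sprintf("termnet_%s_edges.tsv", dir)))
    networks[[dir]] <- tg
    manifest <- c(manifest,
                  sprintf("termnet_%s\tdice_cutoff\t%.6g", dir, tg$cutoff),
                  sprintf("termnet_%s\tedges\t%d", dir, nrow(tg$edges)))
  }

  ## cross-omics integration
  venn <- list(up = venn_counts(lapply(deg_sets$sets, `[[`, "up")),
               down = venn_counts(lapply(deg_sets$sets, `[[`, "down")))
  dec <- config$integrate$decimals
  overlaps <- data.frame(
    quantity = c("up_protein_gene_overlap_pct", "down_protein_gene_overlap_pct",
                 "up_shared_all_cell_types_pct", "down_shared_all_cell_types_pct"),
    value = c(
      if (length(up_prot) > 0)
        overlap_fraction(length(intersect(up_prot, up_genes)), length(up_prot),
                         decimals = dec) else NA_real_,
      if (length(down_prot) > 0)
        overlap_fraction(length(intersect(down_prot, down_genes)),
                         length(down_prot), decimals = dec) else NA_real_,
      if (length(up_genes) > 0)
        overlap_fraction(venn$up$triple, length(up_genes), decimals = dec)
      else NA_real_,
      if (length(down_genes) > 0)
        overlap_fraction(venn$down$triple, length(down_genes), decimals = dec)
      else NA_real_),
    stringsAsFactors = FALSE)
  utils::write.table(overlaps, file.path(out_dir, "overlaps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  venn_df <- do.call(rbind, lapply(names(venn), function(d) {
    data.frame(direction = d, region = names(venn[[d]]$regions),
               count = as.integer(venn[[d]]$regions), stringsAsFactors = FALSE)
  }))
  utils::write.table(venn_df, file.path(out_dir, "venn_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## attribute mapping onto a small synthetic interaction chain over called genes
  pathway <- NULL
  de_union <- sort(unique(c(up_genes, down_genes)))
  if (length(de_union) >= 2) {
    genes <- utils::head(de_union, 20)
    node_kinds <- data.frame(id = c(genes, "M_metab1"),
                             kind = c(rep("gene", length(genes)), "metabolite"),
                             stringsAsFactors = FALSE)
    inter <- data.frame(source = genes[-length(genes)], kind = "reaction",
                        target = genes[-1], stringsAsFactors = FALSE)
    inter <- rbind(inter, data.frame(source = genes[1], kind = "transport",
                                     target = "M_metab1", stringsAsFactors = FALSE))
    pathway <- map_to_pathway(inter, node_kinds, deg_sets,
                              colour_rule = config$integrate$colour_rule)
    write_pathway_graph(pathway,
                        graphml = file.path(out_dir, "pathway.graphml"),
                        nodes_tsv = file.path(out_dir, "pathway_nodes.tsv"))
  }

  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(deg_results = deg_results, dep_results = dep_results,
                 cohort_result = cres, enrichment = enr, shares = shares,
                 networks = networks, venn = venn, overlaps = overlaps,
                 pathway = pathway, manifest = manifest, out_dir = out_dir))
}
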