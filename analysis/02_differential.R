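#!/usr/bin/env Rscript
# Stage 2: permutation-null differential calling.
#
# Per cell type: expressed-gene filter (FPKM >= 1 in all samples), log2(v+1),
# quantile normalization, then the empirical t-test against a pooled
# 1000-permutation null. Transcripts use the fixed thresholds p < 0.05 and
# |log2FC| > 0.58; proteins use p < 0.2 with a null-percentile fold-change
# cutoff and the quartile-mean gap filter; the cohort uses the majority
# expressed filter and a null-percentile cutoff at p < 0.05.

suppressPackageStartupMessages(library(permomics))

dat <- "results/data"
out <- "results/differential"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- default_config(seed = 1L)

expr <- read_omics(file.path(dat, "expression_fpkm.tsv"))
prot <- read_omics(file.path(dat, "protein_abundance.tsv"))
coh <- read_omics(file.path(dat, "cohort_fpkm.tsv"))

for (ct in unique(expr$metadata$cell_type)) {
  sub <- subset_omics(expr, samples = expr$metadata$sample_id[
    expr$metadata$cell_type == ct])
  norm <- quantile_normalize(log_transform(filter_expressed(sub, "all_min")))
  sp <- cell_type_spec(norm, ct, n_permutations = cfg$n_permutations,
                       seed = cfg$seed)
  deg <- run_comparison(norm, sp, preset = "deg")
  write.table(deg$stats, file.path(out, sprintf("deg_%s.tsv", ct)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  psub <- subset_omics(prot, samples = prot$metadata$sample_id[
    prot$metadata$cell_type == ct])
  psp <- cell_type_spec(psub, ct, n_permutations = cfg$n_permutations,
                        seed = cfg$seed)
  dep <- run_comparison(psub, psp, preset = "dep")
  write.table(dep$stats, file.path(out, sprintf("dep_%s.tsv", ct)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("%s: %3d DEGs (%d up / %d down of %d expressed); %3d DEPs, derived |log2FC| cutoff %.3f, gap cutoff %.3f\n",
              ct, sum(deg$stats$call != "ns"),
              sum(deg$stats$call == "up"), sum(deg$stats$call == "down"),
              nrow(deg$stats), sum(dep$stats$call != "ns"),
              dep$cutoffs$fc_cutoff, dep$cutoffs$gap_cutoff))
}

cnorm <- quantile_normalize(log_transform(filter_expressed(coh, "majority")))
csp <- comparison_spec(coh$metadata$sample_id[coh$metadata$group == "A"],
                       coh$metadata$sample_id[coh$metadata$group == "B"],
                       n_permutations = cfg$n_permutations, seed = cfg$seed)
cres <- run_comparison(cnorm, csp, preset = "cohort")
write.table(cres$stats, file.path(out, "cohort.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("cohort: %d called of %d expressed; derived |log2FC| cutoff %.3f\n",
            sum(cres$stats$call != "ns"), nrow(cres$stats),
            cres$cutoffs$fc_cutoff))
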