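#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-omics study inputs.
#
# The design mirrors the study layout the pipeline targets: 3 cell types x
# {control, treated} x 3 replicates for both the transcript (FPKM) and
# protein (normalized log-abundance) layers, a gene-set annotation with four
# level-1 modules, and a down-scaled two-group cohort (20 vs 80). Ground
# truth for every planted effect is written next to each matrix.

suppressPackageStartupMessages(library(permomics))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- default_config(seed = 1L)

design <- do.call(sim_design, c(cfg$design, list(seed = cfg$seed)))
expr <- generate_expression(design)
prot <- generate_proteome(design, coupling = cfg$proteome$coupling,
                          expr_truth = expr$truth,
                          effect_scale = cfg$proteome$effect_scale,
                          noise_scale = cfg$proteome$noise_scale)
ann <- do.call(generate_annotation,
               c(cfg$annotation, list(n_genes = design$n_features,
                                      seed = cfg$seed)))
coh <- do.call(generate_cohort,
               c(cfg$cohort, list(n_features = design$n_features,
                                  seed = cfg$seed)))

write_omics(expr$matrix, file.path(out, "expression_fpkm.tsv"))
write_omics(prot$matrix, file.path(out, "protein_abundance.tsv"))
write_omics(coh$matrix, file.path(out, "cohort_fpkm.tsv"))
write_gmt(ann, file.path(out, "annotation.gmt"))
write_truth(expr$truth, file.path(out, "expression_truth.tsv"))
write_truth(prot$truth, file.path(out, "protein_truth.tsv"))
write_truth(coh$truth, file.path(out, "cohort_truth.tsv"))

cat(sprintf("expression: %d features x %d samples (%d planted up, %d down per cell type)\n",
            nrow(expr$matrix$values), ncol(expr$matrix$values),
            sum(expr$truth$direction == "up" & expr$truth$cell_type == "CT1"),
            sum(expr$truth$direction == "down" & expr$truth$cell_type == "CT1")))
cat(sprintf("proteome:   %d features, coupling %.2f to the expression truth\n",
            nrow(prot$matrix$values), cfg$proteome$coupling))
cat(sprintf("annotation: %d terms over %d modules\n",
            nrow(ann$terms), length(unique(ann$terms$module))))
cat(sprintf("cohort:     %d vs %d samples\n",
            sum(coh$matrix$metadata$group == "A"),
            sum(coh$matrix$metadata$group == "B")))
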