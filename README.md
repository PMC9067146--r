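# permomics

Permutation-null differential analysis and process-network construction for
small replicated multi-omics designs.

## The problem

A common multi-omics design measures a few cell lines before and after a
treatment with three replicates per condition, on both the transcript
(RNA-seq, FPKM) and protein (TMT, normalized log abundance) layers. With
n = 3 per group, parametric t-test p-values are fragile; the approach
implemented here calibrates significance empirically instead:

1. **Normalize** — keep expressed features (FPKM ≥ 1 in all samples, or
   strictly > 1 in a majority for large cohorts), transform to
   log2(FPKM+1), quantile-normalize jointly across the comparison.
2. **Empirical permutation test** — per feature, the Welch t statistic and
   log2 fold change; sample labels permuted 1000 times, statistics pooled
   across features and permutations into an empirical null; two-sided
   empirical p = (1 + #{|t_null| ≥ |t_obs|}) / (1 + N_null).
3. **Call** — transcripts: p < 0.05 and |log2FC| > 0.58. Proteins:
   p < 0.2 with a data-derived fold-change cutoff, the mean of the |2.5th|
   and |97.5th| percentiles of the null log2FC distribution, then a second
   stage keeping features whose range-separation gap
   (min of the high group − max of the low group) exceeds the mean of the
   25th/75th percentiles of the stage-1 gap distribution.
4. **Enrich** — EASE-score gene-set enrichment (hypergeometric upper tail
   with one success removed, p = P(X ≥ k−1)), background = expressed
   features, threshold p < 0.05.
5. **Network** — enriched terms connected when they share ≥ 3 members and
   their Sørensen–Dice coefficient 2|Pi∩Pj|/(|Pi|+|Pj|) exceeds the 95th
   percentile of the candidate-pair distribution; seeded Louvain
   communities labelled by majority level-1 module.
6. **Integrate** — Venn partitions across cell types, mRNA/protein overlap
   percentages, and attribute mapping (max-magnitude log2FC colour,
   DE-cell-type-count label size) onto a SIF interaction table.

A synthetic-data module generates the full study layout (3 cell types ×
{control, treated} × 3 replicates, coupled proteome, module-structured
annotation, 20-vs-80 cohort) with planted effects and ground-truth tables,
so the whole pipeline is testable without downloads.

## Worked example

```r
library(permomics)

design <- sim_design(n_features = 1000, frac_up = 0.05, frac_down = 0.05,
                     effect_log2fc = 1.0, noise_sd = 0.25, seed = 7)
sim <- generate_expression(design)
ct1 <- subset_omics(sim$matrix, samples = sim$matrix$metadata$sample_id[
  sim$matrix$metadata$cell_type == "CT1"])
norm <- quantile_normalize(log_transform(filter_expressed(ct1, "all_min")))
spec <- cell_type_spec(norm, "CT1", n_permutations = 1000, seed = 7)
res <- run_comparison(norm, spec, preset = "deg")
table(res$stats$call)
#> down   ns   up
#>   45  708   47
```

Of the 100 planted features (50 up, 50 down), 88 are recalled at p < 0.05
and |log2FC| > 0.58 — 88% sensitivity against the ground truth at these
noise settings — and the 92 total calls include a handful of false
positives at the nominal rate. The derived fold-change cutoff from this
run's null is

```r
derive_fc_cutoff(res$null)
#> [1] 0.497
```

The numbered scripts under `analysis/` run the full sequence —
`01_simulate.R` through `05_integration.R` — writing each stage's tables
under `results/`, or equivalently `run_pipeline(default_config(seed = 1))`
executes every stage end to end and writes a provenance manifest.

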