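---
title: "Permutation-null multi-omics differential analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-null multi-omics differential analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

permomics implements an empirical, permutation-calibrated differential
analysis for small replicated two-group omics designs — the setting of a
treatment-vs-control experiment run in a few cell lines with three
replicates per condition — together with the downstream process-level
machinery that turns feature calls into interpretable networks: EASE-score
gene-set enrichment, Sørensen–Dice term-association graphs, and cross-omics
overlap statistics. This vignette explains the statistical model, the
tunable parameters, and the design decisions taken where the method
description left genuine freedom.

## The differential model

For each feature (gene or protein) the observed statistic is the Welch
unequal-variance two-sample *t* comparing treated with control replicates on
a log scale, alongside the log2 fold change `log2FC = mean(treated) −
mean(control)`. Significance is not taken from the *t* distribution — with
3 replicates per group the distributional assumptions carry too much weight —
but from an **empirical null**: sample labels are permuted across both
groups (preserving group sizes), the statistic is recomputed for every
feature, and all values are pooled across features and permutations. The
empirical p-value of a feature is the two-sided rank of its observed |t| in
this pooled null,

```
p = (1 + #{ |t_null| >= |t_obs| }) / (1 + N_null),
```

with an add-one correction so p is never exactly zero. Pooling across
features is what makes this p-value "adjusted": each feature is ranked
against the genome-wide null rather than its own 20-odd permutations, which
both smooths the null and tightens its resolution to `1 / (features ×
permutations)`. No additional Benjamini–Hochberg step is applied before
thresholding, because the calling rules act directly on this pooled
empirical p; a BH column (`p_bh`) is emitted alongside for inspection.

Design choices worth stating explicitly:

* **Welch rather than pooled-variance t.** With 3 replicates either choice
  is defensible; Welch is the safer default under variance heterogeneity
  and is identical in distribution under the permutation null's
  exchangeability.
* **Two-sided via |t|**, since both up- and down-regulated features are
  called.
* **Sampled permutations draw label assignments uniformly with
  replacement.** A 3-vs-3 design has only `choose(6,3) = 20` distinct
  assignments, so "1000 permutations" necessarily repeats them. With
  `exhaustive_if_possible = TRUE` the 20 assignments are enumerated exactly
  once instead; the test suite proves the sampled and exhaustive modes agree
  with a brute-force enumerator.
* **Zero-variance guard.** A feature constant within both groups but with
  unequal means gets a signed sentinel t of 1e6 (beyond any finite null
  value); equal means give t = 0.
* **Tie tolerance.** When ranking |t_obs| in the null, values equal up to a
  1e-9 relative tolerance count as ties, so the same split recomputed in a
  different floating-point summation order cannot flip a count.

## Data-derived cutoffs

Transcript calls use fixed thresholds: empirical p < 0.05 and |log2FC| >
0.58 (1.5-fold), both strict. Protein and cohort calls instead derive the
fold-change cutoff from the null itself: the mean of the magnitudes of the
2.5th and 97.5th percentiles of the pooled null log2FC distribution,
`(|q2.5| + |q97.5|)/2`. The mean of *magnitudes* is the only reading that
produces a usable positive cutoff — the signed mean of a near-symmetric
null is approximately zero. All percentiles, here and below, use linear
interpolation between order statistics (R's type 7); the convention is
recorded in each result's provenance because percentile conventions change
derived cutoffs at the second decimal.

Protein calling adds a second stage built on the **gap statistic**: for a
feature, `gap = min(high-mean group) − max(low-mean group)`, positive only
when the replicate ranges separate completely. The gap cutoff is the mean
of the 25th and 75th percentiles of the gap distribution over the stage-1
selected features only, and stage 2 keeps features whose |gap| exceeds it
(a `gap_signed` switch restricts to positive separation instead; the
default follows the absolute-gap reading). Ties in the gap's group
assignment take group A as the high group.

## Normalization

Expressed-feature filtering has two literal modes because the two designs
it serves state different rules: `all_min` keeps features with FPKM ≥ 1 in
*every* sample (cell-line comparisons; inclusive), `majority` keeps
features with FPKM strictly > 1 in strictly more than half the samples
(large cohorts). Both are preserved rather than harmonized. Values then
move to `log2(FPKM + 1)` and are quantile-normalized jointly across all
samples of a comparison (not per group) — joint scope is required for the
permutation null to remain exchangeable. Quantile normalization delegates
to `limma::normalizeQuantiles` with tie averaging (tied values receive the
mean of the reference values across their rank range), verified in the test
suite against a hand rank/row-mean oracle. Normalization is applied per
comparison (per cell type), not globally across cell types.

## Enrichment and term networks

Enrichment uses the EASE score: the one-tailed hypergeometric upper tail
with one overlapping feature removed, `p = P(X ≥ k − 1)` for
`X ~ Hypergeometric(N, K, n)`. The removal makes the score conservative —
provably no smaller than the standard tail — and sends singleton overlaps
to p = 1. The background universe is the set of features passing the
expressed filter, the standard defensible choice when the original
annotation system's internal background is not reproducible; terms are
intersected with this background before testing, and no multiple-testing
correction is applied on top of the 0.05 threshold.

The term-association network connects enriched terms that share at least 3
members and whose Sørensen–Dice coefficient `2|Pi ∩ Pj| / (|Pi| + |Pj|)`
strictly exceeds a cutoff derived as the 95th percentile of the coefficient
distribution over all candidate pairs. The cutoff is derived per direction
(up and down networks separately), which is why the two networks generally
get different cutoffs. Term member sets default to **list-restricted**
membership (members intersected with the direction's query list), because
the coefficient is described as counting features of the analyzed lists
commonly involved in the two terms; `dice_universe = "term"` switches to
full membership. Communities are found with seeded multilevel (Louvain)
modularity optimization — a deterministic, documented substitute for the
interactive community-clustering plugin used in visualization tools, chosen
over greedy agglomeration after the latter proved unable to keep even a
single clique in one community. Each community is labelled with the
majority level-1 module of its terms, ties broken lexicographically.

## Cross-omics integration

Venn partitions across the three cell types, overlap percentages (rounded
half away from zero, matching how such percentages are conventionally
printed), and attribute mapping onto a user-supplied SIF interaction table:
node colour is the log2FC of maximal magnitude across cell types with its
sign retained (`colour_rule = "signed-max"` uses the plain maximum instead;
the magnitude rule is the default because a signed maximum would hide
strong downregulation), and label-size class counts the cell types calling
the gene (3 = large, 2 = middle, 1 = small, 0 = non-DE). Edges naming
unknown nodes are skipped with a warning and counted rather than failing
the run.

## The synthetic-data generators

Every stage is exercised on synthetic data with planted ground truth. The
expression generator emulates the target design — 3 cell types ×
{control, treated} × 3 replicates — with a log-normal feature baseline
(normal on the log2 scale, mean 3, sd 1.5), planted |log2FC| = 1.0 effects
in 5% up + 5% down of features per cell type, replicate noise sd 0.25 on
the log2(FPKM+1) scale, and 80% of features above the expressed filter
(the remainder forced below FPKM 1 in all samples). Noise is log-normal
multiplicative on the FPKM scale — the standard model for FPKM- and
TMT-scale data — which keeps planted log2FC arithmetic exact. No replicate
variance estimates were available for either platform, so the noise sds
are field conventions, chosen once: 0.25 gives a ~80–90% recoverable effect
at n = 3, which matches how such experiments are powered. The protein
generator scales effect (×0.6) and noise (×0.7) so the derived per-cell-line
fold-change cutoffs land in the 0.26–0.33 range typical of TMT reporter
data (closed form: 1.96 · 0.175 · √(2/3) ≈ 0.28), and shares a configurable
fraction (`coupling`, default 0.5) of its planted effects with the paired
expression truth. The annotation generator chains terms within each of four
level-1 modules (metabolism, cell proliferation, cell development, immune
response) so every term shares ≥ 3 members with a same-module partner and
similarity edges are reachable by construction. The cohort generator scales
the 115-vs-535 two-group design down to 20 vs 80 by default (configurable
up), with smaller effects (0.5) and larger per-sample noise (0.5), as
befits tumour heterogeneity.

One global seed fans out to fixed per-generator substreams (offsets +1…+4),
so adding a generator never perturbs existing fixtures, and every generator
is bit-reproducible from its design.

**What the synthetic data does not emulate:** library-size or batch
effects, count noise (values are continuous), correlated features,
annotation terms enriched in the planted effects (planting is independent
of the annotation, so end-to-end enrichment on default simulations is a
negative control — the analysis scripts add a term-coherent positive
control), or the real datasets' abundance distributions. Passing tests
therefore demonstrate calibration and correctness of the machinery, not
performance on real data.

## Problem sizes and numerical notes

Default desk-scale sizes — 2000 features, 1000 permutations, 10-seed
Monte-Carlo repetitions for calibration checks — keep any single comparison
in the low seconds and the whole suite in tens of seconds while leaving the
permutation resolution (1/(features × permutations + 1)) far below every
threshold in use. Real-scale inputs (~20 000 genes, ~9 400 proteins) remain
configurable. Degenerate inputs are handled explicitly: zero-row matrices
survive filtering, a single-feature matrix quantile-normalizes to its row
mean, an empty null or empty candidate-pair set raises an error rather
than returning NaN, and a p-cutoff of 0 produces empty-but-valid outputs
end to end.

## Known limitations

* The empirical p is pooled across features; features with atypical
  variance are ranked against a genome-wide null, which is the method's
  defining trade-off (resolution and stability versus per-feature
  adaptivity).
* With 3-vs-3 designs the permutation space is tiny (20 assignments);
  sampled mode converges to the exhaustive answer but cannot beat its
  granularity.
* The manual curation step that preceded the original protein selection is
  not reproducible and is deliberately absent.
* Community detection on term graphs is a substitute for an interactive
  plugin without a formal specification; communities are a visualization
  aid, not a quantitative claim.
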