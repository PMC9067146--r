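Package: permomics
Title: Permutation-Null Multi-Omics Differential Analysis and Process Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying treatment-responsive genes and
    proteins from replicated two-group omics designs using an empirical
    permutation null: expressed-gene filtering, log2(FPKM+1) transformation and
    quantile normalization; Welch t statistics ranked against a pooled
    permutation null to give empirical p-values; data-derived fold-change
    cutoffs (mean of the 2.5th and 97.5th null percentiles) and a
    range-separation gap filter for protein data; EASE-score gene-set
    enrichment; Sorensen-Dice term-association networks with
    percentile-derived similarity cutoffs and modularity-based communities;
    cross-omics overlap statistics and molecular-network attribute mapping.
    Ships a synthetic-data module with planted effects and ground truth so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
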