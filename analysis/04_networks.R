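#!/usr/bin/env Rscript
# Stage 4: term-association networks.
#
# Nodes are the significantly enriched terms of the positive-control
# enrichment; pairs sharing >= 3 members are scored with the Sorensen-Dice
# coefficient, the edge cutoff is derived at the 95th percentile of the
# candidate coefficient distribution (per direction), and the resulting
# graph is clustered into communities labelled by their majority level-1
# module.

suppressPackageStartupMessages(library(permomics))

dat <- "results/data"
out <- "results/networks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- default_config(seed = 1L)

ann <- read_gmt(file.path(dat, "annotation.gmt"))
enr <- read.table("results/enrichment/enrichment_positive_control.tsv",
                  header = TRUE, sep = "\t", stringsAsFactors = FALSE)

for (dir in c("up", "down")) {
  rows <- enr[enr$direction == dir, , drop = FALSE]
  if (sum(rows$significant) < 2) {
    cat(sprintf("%s: fewer than 2 enriched terms; no network built\n", dir))
    next
  }
  # the direction's feature list: every feature contributing to its rows
  lst <- sort(unique(unlist(lapply(ann$members[rows$term_id[rows$significant]],
                                   identity))))
  g <- build_term_graph(rows, ann, dir, feature_list = lst,
                        min_shared = cfg$network$min_shared,
                        pct = cfg$network$dice_pct,
                        dice_universe = cfg$network$dice_universe)
  g <- cluster_and_group(g)
  write_term_graph(g,
                   graphml = file.path(out, sprintf("termnet_%s.graphml", dir)),
                   edges_tsv = file.path(out, sprintf("termnet_%s_edges.tsv", dir)))
  write.table(g$nodes, file.path(out, sprintf("termnet_%s_nodes.tsv", dir)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s network: %d nodes, %d edges, derived dice cutoff %.3f, %d communities\n",
              dir, nrow(g$nodes), nrow(g$edges), g$cutoff,
              length(unique(g$nodes$community))))
  if (nrow(g$nodes) > 0) {
    print(table(g$nodes$community_module))
  }
}
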