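#!/usr/bin/env Rscript
# Stage 5: cross-omics set algebra and molecular-network attribute mapping.
#
# Venn partitions of the up/down DEG sets across the three cell types,
# mRNA/protein overlap percentages, and attribute mapping (colour =
# largest-magnitude log2FC across cell types; label size = number of cell
# types calling the gene) onto the bundled synthetic interaction table.

suppressPackageStartupMessages(library(permomics))

diffdir <- "results/differential"
out <- "results/integration"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_stats <- function(pattern) {
  files <- list.files(diffdir, pattern = pattern, full.names = TRUE)
  stats <- lapply(files, read.table, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  names(stats) <- sub("^(deg|dep)_(.*)\\.tsv$", "\\2", basename(files))
  stats
}
deg <- call_sets(read_stats("^deg_"))
dep <- call_sets(read_stats("^dep_"))

lines <- character(0)
for (dir in c("up", "down")) {
  v <- venn_counts(lapply(deg$sets, `[[`, dir))
  genes <- sort(unique(unlist(lapply(deg$sets, `[[`, dir))))
  prots <- sort(unique(unlist(lapply(dep$sets, `[[`, dir))))
  shared <- length(intersect(prots, genes))
  pct <- if (length(prots) > 0) overlap_fraction(shared, length(prots)) else NA
  lines <- c(lines, sprintf(
    "%s: %d genes (triple overlap %d, %.1f%% of union); %d proteins, %d (%s%%) also called at the mRNA level",
    dir, v$union, v$triple, 100 * v$triple / max(v$union, 1),
    length(prots), shared, format(pct)))
  venn_df <- data.frame(region = names(v$regions), count = as.integer(v$regions))
  write.table(venn_df, file.path(out, sprintf("venn_%s.tsv", dir)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(lines)
writeLines(lines, file.path(out, "overlap_summary.txt"))

sif <- read_sif(system.file("extdata", "synthetic_pathway.sif",
                            package = "permomics"))
nodes <- read.table(system.file("extdata", "synthetic_pathway_nodes.tsv",
                                package = "permomics"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
pg <- map_to_pathway(sif, nodes, deg)
write_pathway_graph(pg, graphml = file.path(out, "pathway.graphml"),
                    nodes_tsv = file.path(out, "pathway_nodes.tsv"))
cat(sprintf("pathway map: %d nodes (%d genes), %d edges, %d skipped; label classes: %s\n",
            nrow(pg$nodes), sum(pg$nodes$kind == "gene"), nrow(pg$edges),
            pg$n_skipped,
            paste(names(table(pg$nodes$label_class)),
                  table(pg$nodes$label_class), sep = "=", collapse = " ")))
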