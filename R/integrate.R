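#' Three-set Venn region counts
#'
#' Partitions the union of three feature sets into the 7 disjoint Venn
#' regions. Region names use membership masks in the order the sets are
#' given (`"110"` = in sets 1 and 2 only).
#'
#' @param sets Named list of 3 character vectors (e.g. one per cell type).
#' @return A list with `regions` (named integer vector of the 7 disjoint
#'   counts), `triple` (the triple-overlap count) and `union` (union size).
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3) stop("venn_counts expects exactly 3 sets", call. = FALSE)
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  all_keys <- c("100", "010", "001", "110", "101", "011", "111")
  regions <- stats::setNames(integer(length(all_keys)), all_keys)
  if (length(u) > 0) {
    mask <- vapply(sets, function(s) u %in% s, logical(length(u)))
    if (length(u) == 1) mask <- matrix(mask, nrow = 1)
    key <- apply(mask, 1, function(r) paste(as.integer(r), collapse = ""))
    tab <- table(key)
    regions[names(tab)] <- as.integer(tab)
  }
  list(regions = regions, triple = unname(regions["111"]), union = length(u))
}

#' Overlap fraction / percentage with half-away-from-zero rounding
#'
#' @param shared Overlap count (0 <= shared <= total).
#' @param total Denominator (> 0).
#' @param as_percent Multiply by 100.
#' @param decimals Rounding digits (half away from zero).
#' @return The (rounded) fraction or percentage.
#' @export
overlap_fraction <- function(shared, total, as_percent = TRUE, decimals = 1) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (shared < 0 || shared > total) {
    stop("need 0 <= shared <= total", call. = FALSE)
  }
  v <- shared / total
  if (as_percent) v <- 100 * v
  round_half_up(v, decimals)
}

#' Read a SIF-style interaction table
#'
#' Three tab- or space-separated columns: source, interaction kind, target.
#'
#' @param path SIF file path.
#' @return Data frame: `source`, `kind`, `target`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    stop(sprintf("%s:%d: SIF line needs exactly 3 fields", path, bad[1]),
         call. = FALSE)
  }
  data.frame(source = vapply(fields, `[`, "", 1),
             kind = vapply(fields, `[`, "", 2),
             target = vapply(fields, `[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Collect per-cell-type call sets from differential results
#'
#' @param results Named list (by cell type) of stats data frames with `call`
#'   and `log2fc` columns (from [run_comparison()]).
#' @return A `CallSets`: per cell type the up/down id sets and a
#'   feature-by-cell-type log2FC matrix.
#' @export
call_sets <- function(results) {
  stopifnot(length(names(results)) == length(results))
  sets <- lapply(results, function(st) {
    list(up = st$feature_id[st$call == "up"],
         down = st$feature_id[st$call == "down"])
  })
  feats <- sort(unique(unlist(lapply(results, `[[`, "feature_id"))))
  lfc <- sapply(results, function(st) {
    st$log2fc[match(feats, st$feature_id)]
  })
  if (length(feats) == 1) lfc <- matrix(lfc, nrow = 1)
  rownames(lfc) <- feats
  structure(list(sets = sets, log2fc = lfc), class = "CallSets")
}

# Signed value of maximal magnitude across cell types (ties: first column).
absmax_signed <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  v[which.max(abs(v))]
}

#' Map differential calls onto a molecular interaction network
#'
#' Attaches visualization attributes to every gene node of a SIF-style
#' interaction table: node colour value = the log2 fold change of maximal
#' magnitude across the cell types (sign retained; `colour_rule =
#' "signed-max"` uses the plain maximum instead) and label-size class =
#' the number of cell types in which the gene is differentially called
#' (3 = `"large"`, 2 = `"middle"`, 1 = `"small"`, 0 = `"non-DE"`).
#' Edges referencing ids absent from the node table are skipped with a
#' warning and counted.
#'
#' @param interactions Data frame from [read_sif()].
#' @param node_kinds Data frame `id`, `kind` (`gene`, `metabolite`,
#'   `complex`); only `gene` nodes get attributes.
#' @param calls A `CallSets` from [call_sets()].
#' @param colour_rule `"absmax"` (default) or `"signed-max"`.
#' @return A `PathwayGraph`: `nodes` (id, kind, colour, n_de, label_class),
#'   `edges` (kept interactions), `n_skipped` (edge count dropped).
#' @export
map_to_pathway <- function(interactions, node_kinds, calls,
                           colour_rule = c("absmax", "signed-max")) {
  colour_rule <- match.arg(colour_rule)
  stopifnot(inherits(calls, "CallSets"))
  known <- node_kinds$id
  ok <- interactions$source %in% known & interactions$target %in% known
  if (any(!ok)) {
    warning(sum(!ok), " interaction(s) reference unknown nodes; skipped",
            call. = FALSE)
  }
  edges <- interactions[ok, , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- node_kinds
  nodes$colour <- NA_real_
  nodes$n_de <- NA_integer_
  nodes$label_class <- NA_character_
  gene <- nodes$kind == "gene"
  cls <- c("non-DE", "small", "middle", "large")
  for (i in which(gene)) {
    id <- nodes$id[i]
    lfc <- if (id %in% rownames(calls$log2fc)) calls$log2fc[id, ] else NA_real_
    nodes$colour[i] <- if (colour_rule == "absmax") {
      absmax_signed(lfc)
    } else {
      if (all(is.na(lfc))) NA_real_ else max(lfc, na.rm = TRUE)
    }
    n_de <- sum(vapply(calls$sets, function(s) id %in% c(s$up, s$down), logical(1)))
    nodes$n_de[i] <- n_de
    nodes$label_class[i] <- cls[min(n_de, 3) + 1L]
  }
  structure(list(nodes = nodes, edges = edges, n_skipped = sum(!ok),
                 colour_rule = colour_rule),
            class = "PathwayGraph")
}

#' Export a pathway graph
#'
#' @param graph A `PathwayGraph`.
#' @param graphml,nodes_tsv Output paths (either may be `NULL`).
#' @export
write_pathway_graph <- function(graph, graphml = NULL, nodes_tsv = NULL) {
  stopifnot(inherits(graph, "PathwayGraph"))
  if (!is.null(nodes_tsv)) {
    utils::write.table(graph$nodes, nodes_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml)) {
    nd <- graph$nodes
    nd$colour[is.na(nd$colour)] <- 0
    nd$n_de[is.na(nd$n_de)] <- 0L
    nd$label_class[is.na(nd$label_class)] <- "none"
    g <- igraph::graph_from_data_frame(
      graph$edges[, c("source", "target", "kind")], directed = TRUE,
      vertices = nd)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(graph)
}
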