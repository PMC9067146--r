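#' Sorensen-Dice coefficient between two sets
#'
#' `2 |A intersect B| / (|A| + |B|)`; symmetric, in `[0, 1]`.
#'
#' @param set_a,set_b Non-empty character vectors (duplicates ignored).
#' @return The Dice coefficient.
#' @export
dice <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("dice is undefined for empty sets", call. = FALSE)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Candidate term pairs with sufficient shared membership
#'
#' All unordered term pairs sharing at least `min_shared` members, each with
#' its shared count and Dice coefficient.
#'
#' @param members Named list of member-id vectors (one per term).
#' @param min_shared Minimum shared-member count (inclusive), default 3.
#' @return Data frame: `term_i`, `term_j`, `shared`, `dice`.
#' @export
candidate_pairs <- function(members, min_shared = 3) {
  ids <- names(members)
  if (length(ids) < 2) {
    return(data.frame(term_i = character(), term_j = character(),
                      shared = integer(), dice = numeric(),
                      stringsAsFactors = FALSE))
  }
  members <- lapply(members, unique)
  sizes <- lengths(members)
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq.int(i + 1L, length(ids))) {
      s <- length(intersect(members[[i]], members[[j]]))
      if (s >= min_shared) {
        rows[[length(rows) + 1L]] <- data.frame(
          term_i = ids[i], term_j = ids[j], shared = s,
          dice = 2 * s / (sizes[i] + sizes[j]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(term_i = character(), term_j = character(),
                      shared = integer(), dice = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile-derived Dice cutoff
#'
#' The linear-interpolation percentile (default 95th) of the Dice values of
#' all candidate pairs. Computed separately per direction network, so the up
#' and down networks generally get different cutoffs.
#'
#' @param dice_values Numeric vector of candidate-pair Dice coefficients.
#' @param pct Percentile on the 0-100 scale.
#' @return The cutoff (edges then require Dice strictly above it).
#' @export
derive_dice_cutoff <- function(dice_values, pct = 95) {
  if (length(dice_values) == 0) stop("no candidate dice values", call. = FALSE)
  percentile(dice_values, pct)
}

#' Build a term-association graph for one direction
#'
#' Nodes are the enriched terms; edges connect pairs sharing at least
#' `min_shared` members with Dice coefficient strictly above `cutoff`.
#' Isolated nodes are retained. By default each term's member set is
#' restricted to the direction's query list (`dice_universe = "list"`): the
#' coefficient then counts features of the analyzed list commonly involved in
#' the two terms. `dice_universe = "term"` uses full term membership.
#'
#' @param rows Enrichment table from [enrich_lists()] (one direction's
#'   significant rows are used as nodes).
#' @param collection The `GeneSetCollection` supplying member sets.
#' @param direction `"up"` or `"down"`.
#' @param feature_list The direction's feature list (for
#'   `dice_universe = "list"`).
#' @param min_shared Minimum shared members for a candidate pair.
#' @param cutoff Dice cutoff; `NULL` derives it from the candidate pairs at
#'   `pct`.
#' @param pct Percentile used when deriving the cutoff.
#' @param dice_universe `"list"` or `"term"`.
#' @return A `TermGraph`: list with `nodes` (term attributes), `edges`
#'   (`term_i`, `term_j`, `shared`, `dice`), `cutoff`, `min_shared`,
#'   `direction`, `dice_universe`.
#' @export
build_term_graph <- function(rows, collection, direction, feature_list = NULL,
                             min_shared = 3, cutoff = NULL, pct = 95,
                             dice_universe = c("list", "term")) {
  dice_universe <- match.arg(dice_universe)
  stopifnot(inherits(collection, "GeneSetCollection"))
  nodes <- rows[rows$direction == direction & rows$significant, , drop = FALSE]
  members <- collection$members[nodes$term_id]
  if (dice_universe == "list") {
    if (is.null(feature_list)) {
      stop("feature_list required for dice_universe = 'list'", call. = FALSE)
    }
    members <- lapply(members, intersect, y = feature_list)
    keep <- lengths(members) > 0
    nodes <- nodes[keep, , drop = FALSE]
    members <- members[keep]
  }
  pairs <- candidate_pairs(members, min_shared = min_shared)
  if (is.null(cutoff)) {
    cutoff <- if (nrow(pairs) > 0) derive_dice_cutoff(pairs$dice, pct) else NA_real_
  }
  edges <- if (nrow(pairs) > 0 && !is.na(cutoff)) {
    pairs[pairs$dice > cutoff, , drop = FALSE]
  } else {
    pairs[0, , drop = FALSE]
  }
  rownames(edges) <- NULL
  nodes$size <- lengths(members)[nodes$term_id]
  structure(list(nodes = nodes, edges = edges, members = members,
                 cutoff = cutoff, min_shared = min_shared,
                 direction = direction, dice_universe = dice_universe),
            class = "TermGraph")
}

#' @export
print.TermGraph <- function(x, ...) {
  cat(sprintf("TermGraph [%s]: %d terms, %d edges (min shared %d, dice > %.3g)\n",
              x$direction, nrow(x$nodes), nrow(x$edges), x$min_shared, x$cutoff))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("term_i", "term_j"), drop = FALSE],
    directed = FALSE,
    vertices = graph$nodes[, c("term_id", "direction", "p", "module"), drop = FALSE])
  if (nrow(graph$edges) > 0) {
    igraph::E(g)$shared <- graph$edges$shared
    igraph::E(g)$dice <- graph$edges$dice
  }
  g
}

#' Community clustering and module grouping of a term graph
#'
#' Seeded multilevel (Louvain) modularity community detection — a documented
#' substitute for the interactive community-clustering plugin the field's
#' visualization tools provide; each community is then labelled with the
#' majority level-1 module of its member terms, ties broken
#' lexicographically. Isolated nodes form singleton communities. The RNG
#' state is restored afterwards, so clustering never perturbs an enclosing
#' simulation stream.
#'
#' @param graph A `TermGraph` from [build_term_graph()].
#' @param seed Integer seed fixing the community assignment.
#' @return The `TermGraph` with `community` and `community_module` columns
#'   added to `nodes`.
#' @export
cluster_and_group <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "TermGraph"))
  if (nrow(graph$nodes) == 0) {
    graph$nodes$community <- integer(0)
    graph$nodes$community_module <- character(0)
    return(graph)
  }
  g <- as_igraph(graph)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  membership <- igraph::membership(comm)
  graph$nodes$community <- as.integer(membership[graph$nodes$term_id])
  mod_of_comm <- vapply(split(graph$nodes$module, graph$nodes$community),
                        function(mods) {
                          tab <- sort(table(mods), decreasing = TRUE)
                          best <- names(tab)[tab == max(tab)]
                          sort(best)[1]
                        }, character(1))
  graph$nodes$community_module <- mod_of_comm[as.character(graph$nodes$community)]
  graph
}

#' Export a term graph
#'
#' Writes a GraphML file (node attributes: direction, p, module, community;
#' edge attributes: shared, dice) and/or a flat edge-list TSV.
#'
#' @param graph A `TermGraph` (ideally after [cluster_and_group()]).
#' @param graphml,edges_tsv Output paths (either may be `NULL`).
#' @export
write_term_graph <- function(graph, graphml = NULL, edges_tsv = NULL) {
  stopifnot(inherits(graph, "TermGraph"))
  if (!is.null(graphml)) {
    g <- as_igraph(graph)
    if (!is.null(graph$nodes$community)) {
      igraph::V(g)$community <- graph$nodes$community[
        match(igraph::V(g)$name, graph$nodes$term_id)]
    }
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(edges_tsv)) {
    utils::write.table(graph$edges, edges_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(graph)
}
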