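test_that("dice coefficient follows the set formula", {
  expect_equal(dice(c("a", "b", "c", "d"), c("b", "c", "d", "e")), 0.75)
  expect_equal(dice(letters[1:3], letters[1:3]), 1)
  expect_equal(dice(letters[1:3], letters[4:6]), 0)
  expect_error(dice(character(0), "a"), "empty")

  set.seed(31)
  for (i in 1:50) {
    a <- sample(letters, sample(1:15, 1))
    b <- sample(letters, sample(1:15, 1))
    expect_equal(dice(a, b), dice(b, a))
    expect_gte(dice(a, b), 0)
    expect_lte(dice(a, b), 1)
  }
})

test_that("candidate pairs apply the inclusive shared-member floor", {
  mem <- list(T1 = c("a", "b", "c", "d"),
              T2 = c("c", "d", "e", "f"),   # shares 2 with T1
              T3 = c("b", "c", "d", "g"))   # shares 3 with T1, 2 with T2
  pairs <- candidate_pairs(mem, min_shared = 3)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$term_i, "T1")
  expect_equal(pairs$term_j, "T3")
  expect_equal(pairs$shared, 3)
  expect_equal(pairs$dice, 2 * 3 / 8)

  disjoint <- list(A = c("x1", "x2", "x3"), B = c("y1", "y2", "y3"),
                   C = c("z1", "z2", "z3"))
  expect_equal(nrow(candidate_pairs(disjoint)), 0)
})

test_that("dice cutoff derivation uses the linear 95th percentile", {
  vals <- c(rep(0.1, 19), 0.9)
  # order statistic 19.05 under linear interpolation
  expect_equal(derive_dice_cutoff(vals), 0.1 + 0.05 * 0.8, tolerance = 1e-12)

  expect_equal(derive_dice_cutoff(rep(0.4, 10)), 0.4)

  set.seed(12)
  u <- stats::runif(10000)
  expect_equal(derive_dice_cutoff(u), 0.95, tolerance = 0.02)
  expect_error(derive_dice_cutoff(numeric(0)), "candidate")
})

test_that("term-graph edges equal a brute-force all-pairs recomputation", {
  ann <- generate_annotation(n_terms = 60, size_range = c(10, 30),
                             n_genes = 400, n_modules = 4, seed = 9)
  rows <- data.frame(term_id = ann$terms$term_id, direction = "up",
                     p = 0.01, significant = TRUE,
                     module = ann$terms$module, stringsAsFactors = FALSE)
  g <- build_term_graph(rows, ann, "up", min_shared = 3, cutoff = 0.2,
                        dice_universe = "term")
  got <- sort(paste(g$edges$term_i, g$edges$term_j))
  expect_identical(got, brute_force_edges(ann$members, 3, 0.2))

  # strict inequality at the cutoff: an edge exactly at the cutoff is dropped
  mem <- list(A = c("a", "b", "c", "x"), B = c("a", "b", "c", "y"))
  rows2 <- data.frame(term_id = c("A", "B"), direction = "up", p = 0.01,
                      significant = TRUE, module = "metabolism",
                      stringsAsFactors = FALSE)
  coll <- gene_set_collection(
    data.frame(term_id = c("A", "B"), name = c("A", "B"), level = 2,
               module = "metabolism", stringsAsFactors = FALSE), mem)
  d_ab <- dice(mem$A, mem$B)  # 0.75
  at <- build_term_graph(rows2, coll, "up", cutoff = d_ab, dice_universe = "term")
  expect_equal(nrow(at$edges), 0)
  below <- build_term_graph(rows2, coll, "up", cutoff = d_ab - 1e-9,
                            dice_universe = "term")
  expect_equal(nrow(below$edges), 1)

  # monotone pruning: stricter parameters never add edges
  g_strict_shared <- build_term_graph(rows, ann, "up", min_shared = 5,
                                      cutoff = 0.2, dice_universe = "term")
  g_strict_dice <- build_term_graph(rows, ann, "up", min_shared = 3,
                                    cutoff = 0.4, dice_universe = "term")
  key <- function(x) paste(x$edges$term_i, x$edges$term_j)
  expect_true(all(key(g_strict_shared) %in% key(g)))
  expect_true(all(key(g_strict_dice) %in% key(g)))
})

test_that("list-restricted dice universe restricts member sets to the query list", {
  coll <- gene_set_collection(
    data.frame(term_id = c("A", "B"), name = c("A", "B"), level = 2,
               module = "metabolism", stringsAsFactors = FALSE),
    list(A = c("g1", "g2", "g3", "g4", "g5", "h1", "h2"),
         B = c("g1", "g2", "g3", "g6", "h3", "h4")))
  rows <- data.frame(term_id = c("A", "B"), direction = "up", p = 0.01,
                     significant = TRUE, module = "metabolism",
                     stringsAsFactors = FALSE)
  lst <- c("g1", "g2", "g3", "g4", "g5", "g6")
  g <- build_term_graph(rows, coll, "up", feature_list = lst, cutoff = 0.1)
  # restricted sets: A -> g1..g5 (5), B -> g1,g2,g3,g6 (4); shared 3
  expect_equal(g$edges$shared, 3)
  expect_equal(g$edges$dice, 2 * 3 / 9)
  expect_error(build_term_graph(rows, coll, "up", cutoff = 0.1), "feature_list")
})

test_that("community clustering partitions nodes and groups by majority module", {
  # two module-pure cliques with no cross edges -> two communities
  mem <- list(A1 = c("a", "b", "c"), A2 = c("a", "b", "c", "d"),
              B1 = c("x", "y", "z"), B2 = c("x", "y", "z", "w"))
  coll <- gene_set_collection(
    data.frame(term_id = names(mem), name = names(mem), level = 2,
               module = c("metabolism", "metabolism",
                          "immune_response", "immune_response"),
               stringsAsFactors = FALSE), mem)
  rows <- data.frame(term_id = names(mem), direction = "up", p = 0.01,
                     significant = TRUE,
                     module = coll$terms$module, stringsAsFactors = FALSE)
  g <- cluster_and_group(build_term_graph(rows, coll, "up", cutoff = 0.5,
                                          dice_universe = "term"))
  expect_equal(length(unique(g$nodes$community)), 2)
  expect_true(all(table(g$nodes$community) == 2))
  expect_equal(g$nodes$community_module[g$nodes$term_id == "A1"], "metabolism")
  expect_equal(g$nodes$community_module[g$nodes$term_id == "B1"], "immune_response")
  # partition covers all nodes exactly once
  expect_false(any(is.na(g$nodes$community)))

  single <- cluster_and_group(build_term_graph(
    rows[1:2, ], coll, "up", cutoff = 0.5, dice_universe = "term"))
  expect_equal(length(unique(single$nodes$community)), 1)
})

test_that("communities recover planted annotation modules", {
  agree <- vapply(1:5, function(s) {
    ann <- generate_annotation(n_terms = 40, size_range = c(10, 25),
                               n_genes = 2000, n_modules = 4, seed = s)
    rows <- data.frame(term_id = ann$terms$term_id, direction = "up",
                       p = 0.01, significant = TRUE,
                       module = ann$terms$module, stringsAsFactors = FALSE)
    g <- build_term_graph(rows, ann, "up", min_shared = 3, cutoff = 0.1,
                          dice_universe = "term")
    g <- cluster_and_group(g)
    mean(g$nodes$community_module == g$nodes$module)
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})

test_that("graph export writes GraphML and edge TSV", {
  ann <- generate_annotation(n_terms = 20, size_range = c(8, 20),
                             n_genes = 300, n_modules = 4, seed = 14)
  rows <- data.frame(term_id = ann$terms$term_id, direction = "up", p = 0.01,
                     significant = TRUE, module = ann$terms$module,
                     stringsAsFactors = FALSE)
  g <- cluster_and_group(build_term_graph(rows, ann, "up", cutoff = 0.1,
                                          dice_universe = "term"))
  gml <- tempfile(fileext = ".graphml")
  etsv <- tempfile(fileext = ".tsv")
  write_term_graph(g, graphml = gml, edges_tsv = etsv)
  expect_true(file.exists(gml))
  back <- utils::read.table(etsv, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(g$edges))
})
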