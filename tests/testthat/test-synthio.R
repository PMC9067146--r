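test_that("expression generator honours the design arithmetic and is deterministic", {
  d <- sim_design(n_features = 1000, frac_up = 0.05, frac_down = 0.05,
                  effect_log2fc = 1.0, noise_sd = 0.25, seed = 7)
  e1 <- generate_expression(d)
  expect_equal(dim(e1$matrix$values), c(1000, 18))
  tab <- table(e1$truth$direction, e1$truth$cell_type)
  expect_true(all(tab["up", ] == 50))
  expect_true(all(tab["down", ] == 50))
  # bookkeeping conserves counts per cell type
  expect_true(all(colSums(tab) == 1000))
  # planted sign matches direction, null implies zero effect
  expect_true(all(e1$truth$planted_log2fc[e1$truth$direction == "up"] > 0))
  expect_true(all(e1$truth$planted_log2fc[e1$truth$direction == "down"] < 0))
  expect_true(all(e1$truth$planted_log2fc[e1$truth$direction == "null"] == 0))

  e2 <- generate_expression(d)
  expect_identical(e1$matrix$values, e2$matrix$values)
  expect_identical(e1$truth, e2$truth)

  # non-expressed fraction sits below the FPKM filter in every sample
  kept <- filter_expressed(e1$matrix, "all_min")
  expect_lte(nrow(kept$values), round(0.8 * 1000))
})

test_that("invalid designs are rejected", {
  expect_error(sim_design(n_features = 0), "counts")
  expect_error(sim_design(frac_up = 0.7, frac_down = 0.5), "frac_up")
  expect_error(sim_design(noise_sd = -1), "noise_sd")
  expect_error(generate_proteome(sim_design(), coupling = 1.5), "coupling")
  expect_error(generate_cohort(n_group_a = 1), "group sizes")
})

test_that("zero-noise proteome reproduces planted log2FCs exactly", {
  d <- sim_design(n_features = 200, effect_log2fc = 0.5, noise_sd = 0, seed = 3)
  p <- generate_proteome(d, coupling = 0, effect_scale = 1, noise_scale = 1)
  m <- p$matrix
  for (ct in unique(p$truth$cell_type)) {
    tr <- m$metadata$sample_id[m$metadata$cell_type == ct &
                                 m$metadata$condition == "treated"]
    co <- m$metadata$sample_id[m$metadata$cell_type == ct &
                                 m$metadata$condition == "control"]
    lfc <- rowMeans(m$values[, tr]) - rowMeans(m$values[, co])
    truth <- p$truth[p$truth$cell_type == ct, ]
    expect_equal(lfc, stats::setNames(truth$planted_log2fc, truth$feature_id),
                 tolerance = 1e-12)
  }
})

test_that("proteome coupling controls sharing with the expression truth", {
  d <- sim_design(n_features = 1000, seed = 11)
  e <- generate_expression(d)
  p1 <- generate_proteome(d, coupling = 1, expr_truth = e$truth)
  # fully coupled: every planted protein effect matches the expression direction
  for (ct in unique(p1$truth$cell_type)) {
    pt <- p1$truth[p1$truth$cell_type == ct, ]
    et <- e$truth[e$truth$cell_type == ct, ]
    planted <- pt$direction != "null"
    expect_identical(pt$direction[planted], et$direction[planted])
  }
  # uncoupled: overlap of planted sets matches the product of marginals
  overlaps <- vapply(1:20, function(s) {
    ds <- sim_design(n_features = 1000, seed = s)
    es <- generate_expression(ds)
    ps <- generate_proteome(ds, coupling = 0, expr_truth = es$truth)
    eu <- es$truth$feature_id[es$truth$cell_type == "CT1" & es$truth$direction == "up"]
    pu <- ps$truth$feature_id[ps$truth$cell_type == "CT1" & ps$truth$direction == "up"]
    length(intersect(eu, pu)) / length(pu)
  }, numeric(1))
  # marginal up fraction is 0.05; uncoupled planting avoids the expression
  # planted sets, so observed sharing should be near zero, far below coupled
  expect_lt(mean(overlaps), 0.05)
})

test_that("annotation generator produces valid, linked, deterministic collections", {
  a1 <- generate_annotation(n_terms = 50, size_range = c(10, 40),
                            n_genes = 1000, n_modules = 4, seed = 1)
  expect_equal(nrow(a1$terms), 50)
  expect_true(all(lengths(a1$members) >= 10 & lengths(a1$members) <= 40))
  expect_equal(length(unique(a1$terms$module)), 4)

  a2 <- generate_annotation(n_terms = 50, size_range = c(10, 40),
                            n_genes = 1000, n_modules = 4, seed = 1)
  expect_identical(a1$members, a2$members)

  # every term shares >= 3 members with some same-module partner (exhaustive)
  for (i in seq_len(nrow(a1$terms))) {
    same <- setdiff(which(a1$terms$module == a1$terms$module[i]), i)
    shared <- vapply(same, function(j) {
      length(intersect(a1$members[[i]], a1$members[[j]]))
    }, numeric(1))
    expect_gte(max(shared), 3)
  }

  expect_error(generate_annotation(size_range = c(2, 10)), "size_range")
  expect_error(generate_annotation(size_range = c(10, 4000), n_genes = 100),
               "universe")
})

test_that("cohort generator produces a two-group design with reproducible output", {
  c1 <- generate_cohort(n_group_a = 20, n_group_b = 80, n_features = 300, seed = 5)
  expect_equal(ncol(c1$matrix$values), 100)
  expect_equal(sort(unique(c1$matrix$metadata$group)), c("A", "B"))
  expect_equal(sum(c1$matrix$metadata$group == "A"), 20)
  c2 <- generate_cohort(n_group_a = 20, n_group_b = 80, n_features = 300, seed = 5)
  expect_identical(c1$matrix$values, c2$matrix$values)
})
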