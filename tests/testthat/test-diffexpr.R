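spec33 <- function(...) {
  comparison_spec(group_a = c("s1", "s2", "s3"), group_b = c("s4", "s5", "s6"), ...)
}

test_that("observed Welch statistics match the hand formula and guards", {
  v <- rbind(hand = c(3, 4, 5, 1, 2, 3),
             flat = c(2, 2, 2, 1, 1, 1),
             same = c(1, 2, 3, 1, 2, 3))
  st <- observed_stats(toy_matrix(v), spec33())
  expect_equal(st$log2fc, c(2, 1, 0))
  expect_equal(st$t[1], 2 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(st$t[2], 1e6)  # zero variance, unequal means: sentinel
  expect_equal(st$t[3], 0)

  expect_error(observed_stats(toy_matrix(v, "fpkm"), spec33()), "log-scale")
  expect_error(comparison_spec(c("s1", "s2"), c("s2", "s3")), "disjoint")
  expect_error(comparison_spec("s1", c("s2", "s3")), "at least 2")
})

test_that("exhaustive null enumerates all 20 splits of a 3v3 design", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  m <- toy_matrix(v)
  null <- build_null(m, spec33(exhaustive_if_possible = TRUE))
  expect_true(null$exhaustive)
  expect_equal(length(null$t), 20)

  st <- empirical_pvalues(observed_stats(m, spec33(exhaustive_if_possible = TRUE)),
                          null)
  # only the observed split and its mirror reach |t_obs|: p = (1+2)/(1+20)
  expect_equal(st$p_empirical, 3 / 21)

  # sampled mode is reproducible under a fixed seed
  n1 <- build_null(m, spec33(seed = 9))
  n2 <- build_null(m, spec33(seed = 9))
  expect_identical(n1$t, n2$t)
  expect_false(n1$exhaustive)
  expect_equal(length(n1$t), 1000)
})

test_that("empirical p-values follow the add-one two-sided counting rule", {
  toy_null <- structure(list(t = c(-2, -1, 0, 1, 2), log2fc = numeric(5),
                             n_permutations = 5, exhaustive = FALSE,
                             seed = 1L, n_features = 1L),
                        class = "NullDistribution")
  st <- data.frame(feature_id = c("a", "b"), mean_a = 0, mean_b = 0,
                   log2fc = 0, t = c(1.5, 0))
  out <- empirical_pvalues(st, toy_null)
  expect_equal(out$p_empirical, c((1 + 2) / 6, 1))

  big_null <- structure(list(t = stats::rnorm(10000), log2fc = numeric(1),
                             n_permutations = 1, exhaustive = FALSE,
                             seed = 1L, n_features = 1L),
                        class = "NullDistribution")
  st2 <- data.frame(feature_id = "x", mean_a = 0, mean_b = 0, log2fc = 0, t = 99)
  expect_equal(empirical_pvalues(st2, big_null)$p_empirical, 1 / 10001)
})

test_that("pooled exhaustive p-values equal the brute-force enumeration", {
  set.seed(21)
  v <- matrix(stats::rnorm(25 * 6), 25, 6)
  m <- toy_matrix(v)
  sp <- spec33(exhaustive_if_possible = TRUE)
  st <- empirical_pvalues(observed_stats(m, sp), build_null(m, sp))
  expect_equal(st$p_empirical, unname(brute_force_pooled_p(v, 1:3, 4:6)),
               tolerance = 1e-12)
})

test_that("swapping the groups negates effects and preserves p-values", {
  set.seed(5)
  v <- matrix(stats::rnorm(30 * 6), 30, 6)
  m <- toy_matrix(v)
  sp <- spec33(exhaustive_if_possible = TRUE)
  sp_rev <- comparison_spec(sp$group_b, sp$group_a, exhaustive_if_possible = TRUE)
  a <- empirical_pvalues(observed_stats(m, sp), build_null(m, sp))
  b <- empirical_pvalues(observed_stats(m, sp_rev), build_null(m, sp_rev))
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$t, -a$t)
  expect_equal(b$p_empirical, a$p_empirical)
})

test_that("fold-change cutoff derivation uses linear percentile magnitudes", {
  # hand values: |q2.5| = 0.30, q97.5 = 0.26 -> 0.28
  null_vals <- c(rep(-0.30, 50), rep(0, 900), rep(0.26, 50))
  expect_equal(derive_fc_cutoff(null_vals), (0.30 + 0.26) / 2, tolerance = 1e-12)

  sym <- c(-3, -2, -1, 0, 1, 2, 3)
  expect_equal(derive_fc_cutoff(sym), abs(percentile(sym, 97.5)), tolerance = 1e-12)

  set.seed(8)
  z <- stats::rnorm(10000)
  expect_equal(derive_fc_cutoff(z), 1.96, tolerance = 0.05)
  # sign-flip invariance
  expect_equal(derive_fc_cutoff(-z), derive_fc_cutoff(z), tolerance = 1e-12)

  expect_error(derive_fc_cutoff(numeric(0)), "empty")
})

test_that("gap statistic and its quartile-mean cutoff match hand values", {
  expect_equal(compute_gap(c(5, 6, 7), c(1, 2, 3)), 2)
  expect_equal(compute_gap(c(4, 6, 7), c(1, 5, 3)), -1)
  g <- c(1, 2, 3)
  expect_equal(compute_gap(g, g), min(g) - max(g))
  expect_error(compute_gap(numeric(0), 1), "non-empty")

  expect_equal(derive_gap_cutoff(c(0.02, 0.05, 0.07, 0.10)), 0.06,
               tolerance = 1e-12)
  expect_equal(derive_gap_cutoff(rep(0.3, 5)), 0.3)
  two <- derive_gap_cutoff(c(0.1, 0.5))
  expect_gte(two, 0.1)
  expect_lte(two, 0.5)
  expect_error(derive_gap_cutoff(numeric(0)), "empty")
})

test_that("calling applies strict thresholds and the two-stage gap rule", {
  deg_cuts <- cutoff_set(0.05, 0.58)
  st <- data.frame(feature_id = c("a", "b", "c"),
                   log2fc = c(0.60, 0.58, -0.70),
                   p_empirical = c(0.04, 0.04, 0.2))
  out <- call_features(st, deg_cuts)
  expect_equal(out$call, c("up", "ns", "ns"))  # 0.58 exactly fails strict >

  dep_cuts <- cutoff_set(0.2, 0.28, "null_percentile",
                         gap_cutoff = 0.06, gap_mode = "quartile_mean")
  st2 <- data.frame(feature_id = c("a", "b"),
                    log2fc = c(0.30, 0.30),
                    p_empirical = c(0.15, 0.15),
                    gap = c(0.05, 0.10))
  out2 <- call_features(st2, dep_cuts)
  expect_equal(out2$call, c("ns", "up"))  # fails / passes the gap stage
})

test_that("run_comparison presets audit their own postconditions", {
  d <- sim_design(n_features = 400, seed = 7)
  e <- generate_expression(d)
  samples <- e$matrix$metadata$sample_id[e$matrix$metadata$cell_type == "CT1"]
  norm <- quantile_normalize(log_transform(
    filter_expressed(subset_omics(e$matrix, samples = samples), "all_min")))
  sp <- cell_type_spec(norm, "CT1", n_permutations = 200, seed = 7)
  res <- run_comparison(norm, sp, preset = "deg")
  called <- res$stats[res$stats$call != "ns", ]
  expect_true(all(called$p_empirical < 0.05 & abs(called$log2fc) > 0.58))
  expect_true(all(res$stats$p_empirical > 0 & res$stats$p_empirical <= 1))

  # dep preset: stage-2 calls are a subset of the stage-1 selection
  p <- generate_proteome(d, coupling = 0.5, expr_truth = e$truth)
  psub <- subset_omics(p$matrix,
                       samples = p$matrix$metadata$sample_id[
                         p$matrix$metadata$cell_type == "CT1"])
  psp <- cell_type_spec(psub, "CT1", n_permutations = 200, seed = 7)
  pres <- run_comparison(psub, psp, preset = "dep")
  stage1 <- pres$stats$p_empirical < pres$cutoffs$p_cutoff &
    abs(pres$stats$log2fc) > pres$cutoffs$fc_cutoff
  expect_true(all(pres$stats$call[!stage1] == "ns"))
  expect_gt(pres$cutoffs$fc_cutoff, 0)

  expect_error(run_comparison(psub, psp, preset = "deg"), "layer")

  # degenerate p_cutoff = 0 yields zero calls but a valid table
  res0 <- run_comparison(norm, sp, preset = "deg", p_cutoff = 0)
  expect_true(all(res0$stats$call == "ns"))
})
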