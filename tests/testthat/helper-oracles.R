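# Independent oracles used across the suite. These deliberately use different
# code paths from the package (stats::t.test, explicit loops, dhyper sums).

# Small OmicsMatrix from a plain matrix, with generic two-group metadata.
toy_matrix <- function(values, layer = "lognorm") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  meta <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  omics_matrix(values, meta, layer = layer)
}

# Brute-force pooled exhaustive permutation p-values on a 3-vs-3 design,
# computing every Welch t with stats::t.test over all choose(6, 3) splits.
brute_force_pooled_p <- function(values, ia, ib) {
  n_tot <- length(c(ia, ib))
  union_idx <- c(ia, ib)
  splits <- utils::combn(n_tot, length(ia))
  pool <- c()
  for (b in seq_len(ncol(splits))) {
    ga <- union_idx[splits[, b]]
    gb <- union_idx[-splits[, b]]
    pool <- c(pool, apply(values, 1, function(v) {
      unname(stats::t.test(v[ga], v[gb])$statistic)
    }))
  }
  t_obs <- apply(values, 1, function(v) {
    unname(stats::t.test(v[ia], v[ib])$statistic)
  })
  vapply(t_obs, function(t) {
    (1 + sum(abs(pool) >= abs(t) - 1e-9)) / (1 + length(pool))
  }, numeric(1))
}

# Hand quantile normalization: reference = mean of per-rank sorted values;
# ties within a column get the mean of the reference over their rank range.
qn_oracle <- function(X) {
  ref <- rowMeans(apply(X, 2, sort))
  out <- X
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j], ties.method = "min")
    r_max <- rank(X[, j], ties.method = "max")
    out[, j] <- vapply(seq_len(nrow(X)), function(i) {
      mean(ref[r[i]:r_max[i]])
    }, numeric(1))
  }
  out
}

# Explicit hypergeometric upper-tail sum.
hyper_tail <- function(N, K, n, k_min) {
  if (k_min <= 0) return(1)
  sum(stats::dhyper(k_min:min(n, K), K, N - K, n))
}

# All-pairs term-graph edge recomputation, independent of candidate_pairs.
brute_force_edges <- function(members, min_shared, cutoff) {
  ids <- names(members)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      a <- unique(members[[i]])
      b <- unique(members[[j]])
      s <- sum(a %in% b)
      d <- 2 * s / (length(a) + length(b))
      if (s >= min_shared && d > cutoff) {
        rows[[length(rows) + 1L]] <- paste(ids[i], ids[j])
      }
    }
  }
  sort(unlist(rows))
}
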