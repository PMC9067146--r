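#' EASE-score enrichment p-value
#'
#' The EASE score is a conservative variant of the one-tailed
#' Fisher/hypergeometric enrichment p-value: one overlapping gene is removed
#' before computing the upper tail, `p = P(X >= k - 1)` for
#' `X ~ Hypergeometric(N, K, n)`. An overlap of 0 (or 1, after the removal)
#' gives p = 1.
#'
#' @param N Background universe size.
#' @param K Term size within the background.
#' @param n Query list size.
#' @param k Overlap between list and term.
#' @return The EASE p-value in (0, 1].
#' @export
ease_pvalue <- function(N, K, n, k) {
  if (k < 0 || k > min(n, K) || K > N || n > N) {
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N", call. = FALSE)
  }
  if (k == 0) return(1)
  # P(X >= k - 1) = P(X > k - 2)
  stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

#' Enrich up/down feature lists against a gene-set collection
#'
#' Term member sets are intersected with the background before testing; one
#' row is produced per (term, direction) with overlap k >= 1, flagged
#' significant when the EASE p-value is strictly below `p_cutoff`. No
#' multiple-testing correction is applied: the threshold acts on the raw
#' EASE p.
#'
#' @param up,down Character vectors of feature ids (subsets of `background`).
#' @param collection A `GeneSetCollection`.
#' @param background Character vector: the tested universe (typically the
#'   features passing the expressed filter).
#' @param p_cutoff Significance threshold on the EASE p (strict <).
#' @return Data frame (`EnrichmentRow`s): `term_id`, `direction`, `n`, `K`,
#'   `N`, `k`, `p`, `significant`, `module`, `level`; sorted by `p` within
#'   direction.
#' @export
enrich_lists <- function(up, down, collection, background, p_cutoff = 0.05) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (length(background) == 0) stop("empty background", call. = FALSE)
  background <- unique(background)
  N <- length(background)
  lists <- list(up = intersect(up, background), down = intersect(down, background))
  rows <- list()
  for (dir in names(lists)) {
    lst <- lists[[dir]]
    n <- length(lst)
    if (n == 0) next
    for (i in seq_len(nrow(collection$terms))) {
      tid <- collection$terms$term_id[i]
      mem <- intersect(collection$members[[tid]], background)
      K <- length(mem)
      if (K == 0) next
      k <- length(intersect(lst, mem))
      if (k == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = tid, direction = dir, n = n, K = K, N = N, k = k,
        p = ease_pvalue(N, K, n, k),
        module = collection$terms$module[i],
        level = collection$terms$level[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(term_id = character(), direction = character(),
                      n = integer(), K = integer(), N = integer(),
                      k = integer(), p = numeric(), module = character(),
                      level = integer(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < p_cutoff
  out <- out[order(out$direction, out$p), ]
  rownames(out) <- NULL
  out
}

#' Summarize enriched terms by level-1 module
#'
#' Computes, per direction, the percentage of significantly enriched terms
#' falling in each level-1 module (the pie-chart shares of the process-level
#' summary). Percentages are rounded half away from zero and sum to 100 up
#' to rounding.
#'
#' @param rows Enrichment table from [enrich_lists()].
#' @param decimals Digits for the percentage.
#' @return Data frame: `direction`, `module`, `n_terms`, `percent`.
#' @export
categorize_level1 <- function(rows, decimals = 1) {
  if (is.null(rows$module) || any(is.na(rows$module) | rows$module == "")) {
    stop("every term must carry a module label", call. = FALSE)
  }
  sig <- rows[rows$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(direction = character(), module = character(),
                      n_terms = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (dir in unique(sig$direction)) {
    sub <- sig[sig$direction == dir, ]
    tab <- table(sub$module)
    out[[dir]] <- data.frame(direction = dir, module = names(tab),
                             n_terms = as.integer(tab),
                             percent = round_half_up(100 * as.integer(tab) / nrow(sub),
                                                     decimals),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write gene sets in GMT format
#'
#' Tab-separated: term id, description, members... The description encodes
#' the term's level and level-1 module as `level|module`.
#'
#' @param collection A `GeneSetCollection`.
#' @param path GMT file path.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` a
#'   `GeneSetCollection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(seq_len(nrow(collection$terms)), function(i) {
    t <- collection$terms[i, ]
    paste(c(t$term_id, sprintf("%d|%s", t$level, t$module),
            collection$members[[t$term_id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop(sprintf("%s:%d: GMT line needs term, description and >= 1 member",
                 path, bad[1]), call. = FALSE)
  }
  terms <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    desc <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    if (length(desc) != 2 || is.na(suppressWarnings(as.integer(desc[1])))) {
      stop(sprintf("%s:%d: description must be 'level|module'", path, i),
           call. = FALSE)
    }
    data.frame(term_id = f[1], name = f[1], level = as.integer(desc[1]),
               module = desc[2], stringsAsFactors = FALSE)
  })
  members <- lapply(fields, function(f) f[-(1:2)])
  terms <- do.call(rbind, terms)
  names(members) <- terms$term_id
  gene_set_collection(terms, members)
}
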