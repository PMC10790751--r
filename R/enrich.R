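# Category enrichment among non-shared genes: are the genes that differ
# between very close genome pairs (ANI > 99.8%) more often hypothetical /
# mobile than the genes that differ between divergent pairs of the same
# species?

#' Pool non-shared gene categories for close vs divergent pairs
#'
#' Counts `hypothetical/mobile` vs total non-shared genes across close pairs
#' (ANI > `close_min`) and divergent pairs (ANI within `divergent_range`),
#' with each gene occurrence counted once per pair. The two groups are
#' disjoint by construction.
#'
#' @param pairs `ani_pair_table`.
#' @param gene_shares list of [shared_gene_fraction()] results aligned with
#'   the rows of `pairs`.
#' @param close_min lower ANI bound (exclusive) of the close group.
#' @param divergent_range inclusive ANI range of the divergent group.
#' @return object of class `nonshared_counts`: per group, `k` (mobile) and
#'   `n` (total non-shared gene occurrences), plus pair counts.
#' @export
collect_nonshared <- function(pairs, gene_shares, close_min = 99.8,
                              divergent_range = c(96, 99.8)) {
  stopifnot(nrow(pairs) == length(gene_shares))
  grp <- ifelse(!is.na(pairs$ani) & pairs$ani > close_min, "close",
         ifelse(!is.na(pairs$ani) & pairs$ani >= divergent_range[1] &
                  pairs$ani <= divergent_range[2], "divergent", NA))
  count <- function(which_grp) {
    k <- n <- 0L; np <- 0L
    for (i in which(!is.na(grp) & grp == which_grp)) {
      gs <- gene_shares[[i]]
      cats <- c(gs$nonshared_a$category, gs$nonshared_b$category)
      k <- k + sum(cats == "hypothetical/mobile")
      n <- n + length(cats)
      np <- np + 1L
    }
    list(k = k, n = n, n_pairs = np)
  }
  structure(list(close = count("close"), divergent = count("divergent"),
                 close_min = close_min, divergent_range = divergent_range),
            class = "nonshared_counts")
}

#' Two-proportion z-test
#'
#' Pooled-variance two-proportion z statistic for `k_A/n_A` vs `k_B/n_B`,
#' with a two-sided normal p-value: the test behind the observation that
#' genes differing between >99.8%-ANI genome pairs are enriched in
#' hypothetical and mobile functions.
#'
#' @param k_A,n_A successes and trials in group A (close pairs).
#' @param k_B,n_B successes and trials in group B (divergent pairs).
#' @return object of class `enrichment_result` with fields `z`, `p_value`,
#'   the group proportions and the pooled proportion. `z` is `NA`-flagged
#'   when the pooled proportion is 0 or 1.
#' @export
#' @examples
#' two_proportion_z(50, 100, 30, 100)  # z = 2.8868, p ~ 0.0039
two_proportion_z <- function(k_A, n_A, k_B, n_B) {
  if (n_A < 1L || n_B < 1L) stop("both groups need at least one observation")
  if (k_A < 0 || k_A > n_A || k_B < 0 || k_B > n_B) stop("need 0 <= k <= n")
  pA <- k_A / n_A; pB <- k_B / n_B
  pooled <- (k_A + k_B) / (n_A + n_B)
  if (pooled <= 0 || pooled >= 1) {
    z <- NA_real_; p <- NA_real_
  } else {
    z <- (pA - pB) / sqrt(pooled * (1 - pooled) * (1 / n_A + 1 / n_B))
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(k_A = k_A, n_A = n_A, k_B = k_B, n_B = n_B,
                 prop_A = pA, prop_B = pB, pooled = pooled,
                 z = z, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d/%d (%.3f) vs %d/%d (%.3f): z = %s, two-sided p = %s\n",
              x$k_A, x$n_A, x$prop_A, x$k_B, x$n_B, x$prop_B,
              format(x$z, digits = 5), format(x$p_value, digits = 4)))
  invisible(x)
}

#' Permutation reference for the two-proportion test
#'
#' Reassigns the pooled Bernoulli outcomes to the two groups at random and
#' returns the two-sided permutation p-value of the difference in
#' proportions. Used as an independent check on [two_proportion_z()].
#'
#' @inheritParams two_proportion_z
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @return permutation p-value (with +1 continuity correction).
#' @export
two_proportion_perm <- function(k_A, n_A, k_B, n_B, n_perm = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- abs(k_A / n_A - k_B / n_B)
  pool <- c(rep(1L, k_A + k_B), rep(0L, n_A + n_B - k_A - k_B))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n_A)
    ka <- sum(pool[idx]); kb <- (k_A + k_B) - ka
    if (abs(ka / n_A - kb / n_B) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Enrichment of mobile categories among non-shared genes
#'
#' Convenience wrapper: [collect_nonshared()] then [two_proportion_z()].
#' Refuses to test when either group is empty.
#'
#' @inheritParams collect_nonshared
#' @return `enrichment_result` with the `nonshared_counts` attached.
#' @export
enrichment_test <- function(pairs, gene_shares, close_min = 99.8,
                            divergent_range = c(96, 99.8)) {
  counts <- collect_nonshared(pairs, gene_shares, close_min, divergent_range)
  if (counts$close$n == 0L || counts$divergent$n == 0L)
    stop("empty group: need non-shared genes in both close and divergent pairs")
  res <- two_proportion_z(counts$close$k, counts$close$n,
                          counts$divergent$k, counts$divergent$n)
  res$counts <- counts
  res
}
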