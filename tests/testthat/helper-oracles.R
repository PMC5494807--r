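# Independent brute-force oracles used to pin expected values.
# These deliberately use plain loops / explicit enumeration and share no code
# with the package implementation.

# Running-sum enrichment score by explicit walk over the ranking.
# `hit` is a logical vector over ranks; `weights` the per-rank weight used on
# hits (defaults to 1 = unweighted). Returns the signed maximum-magnitude
# deviation, first occurrence on ties.
oracle_es <- function(hit, weights = rep(1, length(hit))) {
  n <- length(hit)
  n_hit <- sum(hit)
  total_w <- sum(weights[hit])
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) running <- running + weights[i] / total_w
    else running <- running - 1 / (n - n_hit)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of the pooled ranks to group A (ties not supported).
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  n1 <- length(a)
  obs_w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for A
  splits <- combn(length(pooled), n1)
  all_w <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(all_w <= obs_w), mean(all_w >= obs_w))
  min(p, 1)
}

# Hypergeometric upper tail P(X >= k) by explicit choose() summation.
oracle_hypergeom_p <- function(k, n_a, n_b, universe) {
  ks <- k:min(n_a, n_b)
  sum(choose(n_a, ks) * choose(universe - n_a, n_b - ks)) / choose(universe, n_b)
}

# Exhaustive gene-label permutation p for a set of size k in a ranking of
# size N: two-sided exceedance fraction of |ES| over all placements.
oracle_exhaustive_perm_p <- function(ranked_scores, hit_positions, weighted = FALSE) {
  N <- length(ranked_scores)
  k <- length(hit_positions)
  es_of <- function(pos) {
    hit <- seq_len(N) %in% pos
    w <- if (weighted) abs(ranked_scores) else rep(1, N)
    oracle_es(hit, w)
  }
  obs <- es_of(hit_positions)
  all_es <- apply(combn(N, k), 2, es_of)
  mean(abs(all_es) >= abs(obs))
}
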