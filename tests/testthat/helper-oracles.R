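# Independent oracles used across tests: brute-force enumeration for the
# exact Wilcoxon rank-sum p-value, direct step-up arithmetic for BH, and
# Euclidean geometry for ordination checks.

# Two-sided exact rank-sum p by exhaustive enumeration of all C(n1+n2, n1)
# rank assignments (tie-free data only).
exhaustive_wilcox_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n, n1)
  w_all <- apply(subsets, 2L, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Benjamini-Hochberg step-up q-values computed directly from the
# definition: q_(i) = min_{j >= i} ( n * p_(j) / j ).
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(n * p[o] / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Labeled Euclidean distance matrix from a point cloud (rows = samples).
points_to_distances <- function(pts, labels = NULL) {
  d <- as.matrix(stats::dist(pts))
  labels <- labels %||% sprintf("s%02d", seq_len(nrow(pts)))
  dimnames(d) <- list(labels, labels)
  d
}

# Axis-1 group separation: |mean difference| / pooled within-group SD.
axis1_separation <- function(ord, labels) {
  v <- ord$coordinates[, 1]
  labels <- unname(labels[ord$sample_ids])
  gs <- split(v, labels)
  stopifnot(length(gs) == 2L)
  pooled <- sqrt(mean(vapply(gs, stats::var, numeric(1))))
  abs(mean(gs[[1]]) - mean(gs[[2]])) / pooled
}

`%||%` <- function(a, b) if (is.null(a)) b else a
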