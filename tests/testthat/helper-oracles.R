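# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (path walking, double loops, full enumeration) so
# they share no code path with the implementation they check.

random_test_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)  # random topology, uniform branch lengths
  tr$tip.label <- paste0("T", seq_len(n))
  tr
}

# Patristic distance by explicitly walking both tips' root paths and
# summing edge lengths over the symmetric difference.
oracle_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    nodes <- integer(0)
    while (parent[v] != 0L) {
      nodes <- c(nodes, v)
      v <- parent[v]
    }
    nodes
  }
  dm <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    pi <- path_to_root(i)
    for (j in (i + 1):n) {
      pj <- path_to_root(j)
      shared <- intersect(pi, pj)
      d <- sum(elen[setdiff(pi, shared)]) + sum(elen[setdiff(pj, shared)])
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

oracle_mpd <- function(sample, dm) {
  tot <- 0; np <- 0
  for (i in seq_along(sample)) {
    for (j in seq_along(sample)) {
      if (i < j) { tot <- tot + dm[sample[i], sample[j]]; np <- np + 1 }
    }
  }
  tot / np
}

oracle_mntd <- function(sample, dm) {
  mins <- numeric(length(sample))
  for (i in seq_along(sample)) {
    best <- Inf
    for (j in seq_along(sample)) {
      if (i != j) best <- min(best, dm[sample[i], sample[j]])
    }
    mins[i] <- best
  }
  mean(mins)
}

# Upper-tail hypergeometric P(X >= q): q successes among n_node draws
# from a population of n_tips with k_sample successes.
oracle_hyper_upper <- function(q, n_tips, k_sample, n_node) {
  stats::phyper(q - 1, m = k_sample, n = n_tips - k_sample, k = n_node,
                lower.tail = FALSE)
}

# Two-sided rank-sum p by enumerating every assignment of the pooled
# (possibly tied) values to the two groups.
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  rk <- rank(c(a, b))
  mu <- n1 * n2 / 2
  obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  hits <- 0
  for (c in seq_len(ncol(combos))) {
    u <- sum(rk[combos[, c]]) - n1 * (n1 + 1) / 2
    if (abs(u - mu) >= abs(obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / ncol(combos)
}

# Mid-rank Pearson correlation written out longhand.
oracle_midrank_rho <- function(x, y) {
  midrank <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    out
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
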