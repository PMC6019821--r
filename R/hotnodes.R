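#' Per-node over-representation test for a focal tip set
#'
#' For every internal node except the root, counts how many tips of
#' `sample` (e.g. the ethnomedicinally used species) descend from it, and
#' compares that count with its distribution when tip labels are shuffled
#' uniformly across the tree (`runs` relabelings).  The same relabeling is
#' evaluated at every node within a run, giving a valid joint null.  The
#' upper-tail p-value
#' `p_upper = (#\{null >= obs\} + 1) / (runs + 1)` measures
#' over-representation; nodes with `p_upper <= alpha` are flagged
#' significant.  Under-representation (`p_lower`) is reported but never
#' flagged, since only enrichment ("hotnodes") is interpreted.  The root
#' is excluded because its count always equals `|sample|`.
#'
#' @param tree A rooted `"phylo"` object.
#' @param sample Character vector of focal tip labels (non-empty, subset of
#'   the tree's tips).
#' @param runs Number of relabelings (default 999).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param seed Optional integer seed.
#' @param p_adjust Multiple-testing correction applied to `p_upper` before
#'   flagging: `"none"` (default, the conventional usage) or `"BH"`.
#' @return A data frame of class `"nodesig_result"`, one row per non-root
#'   internal node: `node` (ape node id), `n_node_tips`,
#'   `n_sample_in_node`, `n_null_ge` (null exceedance count), `p_upper`,
#'   `p_lower`, `significant`.  Attributes `runs`, `alpha`, `seed`,
#'   `p_adjust`, `n_tips`, `n_sample` record the call.
#' @examples
#' tr <- read_newick("(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
#' ns <- nodesig(tr, c("A", "B", "C", "D"), runs = 199, seed = 1)
#' ns[ns$significant, ]
#' @export
nodesig <- function(tree, sample, runs = 999, alpha = 0.05, seed = NULL,
                    p_adjust = c("none", "BH")) {
  stopifnot(inherits(tree, "phylo"), runs >= 1)
  p_adjust <- match.arg(p_adjust)
  if (length(sample) == 0L) stop("sample is empty")
  if (anyDuplicated(sample)) stop("duplicate labels in sample")
  s_idx <- match(sample, tree$tip.label)
  if (anyNA(s_idx))
    stop("labels not in tree: ", paste(sample[is.na(s_idx)], collapse = ", "))

  n <- ape::Ntip(tree)
  k <- length(s_idx)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  desc <- descendant_tips(tree)
  nodes <- setdiff((n + 1):(n + tree$Nnode), root)
  if (length(nodes) == 0L)
    stop("tree has no non-root internal nodes")

  # node-by-tip membership indicator; one matmul per null matrix
  M <- matrix(0, nrow = length(nodes), ncol = n)
  for (i in seq_along(nodes)) M[i, desc[[nodes[i] - n]]] <- 1
  s <- numeric(n); s[s_idx] <- 1
  obs <- as.vector(M %*% s)

  if (!is.null(seed)) set.seed(seed)
  S <- matrix(0, nrow = n, ncol = runs)
  for (r in seq_len(runs)) S[sample.int(n, k), r] <- 1
  null_counts <- M %*% S

  n_ge <- rowSums(null_counts >= obs)
  n_le <- rowSums(null_counts <= obs)
  p_upper <- (n_ge + 1) / (runs + 1)
  p_lower <- (n_le + 1) / (runs + 1)
  p_flag <- if (p_adjust == "BH") stats::p.adjust(p_upper, "BH") else p_upper

  out <- data.frame(
    node = nodes,
    n_node_tips = rowSums(M),
    n_sample_in_node = as.integer(obs),
    n_null_ge = as.integer(n_ge),
    p_upper = p_upper,
    p_lower = p_lower,
    significant = p_flag <= alpha
  )
  attr(out, "runs") <- runs
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "p_adjust") <- p_adjust
  attr(out, "n_tips") <- n
  attr(out, "n_sample") <- k
  class(out) <- c("nodesig_result", "data.frame")
  out
}

#' Assemble maximal hotnode clades and the inside/outside tip partition
#'
#' Keeps the significant nodes that have no significant ancestor
#' ("maximal" nodes), so the reported clades are disjoint and none is
#' nested inside another; the union of their descendant tips is the
#' "inside hotnode clades" set and its complement the "outside" set.
#' Set `maximal_only = FALSE` to list every significant node instead
#' (the inside/outside partition is unchanged, since nested nodes add no
#' tips).
#'
#' @param results A `"nodesig_result"` from [nodesig()] on `tree`.
#' @param tree The same tree the results were computed on.
#' @param maximal_only Keep only significant nodes without a significant
#'   ancestor (default `TRUE`).
#' @return A list of class `"hotnode_set"`: `nodes` (kept node ids),
#'   `inside`, `outside` (character vectors of tip labels, disjoint,
#'   jointly covering all tips).
#' @export
hotnode_clades <- function(results, tree, maximal_only = TRUE) {
  stopifnot(inherits(results, "nodesig_result"), inherits(tree, "phylo"))
  if (attr(results, "n_tips") != ape::Ntip(tree))
    stop("results were not computed on this tree")
  n <- ape::Ntip(tree)
  sig <- results$node[results$significant]
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  keep <- sig
  if (maximal_only && length(sig)) {
    has_sig_anc <- vapply(sig, function(v) {
      v <- parent[v]
      while (v != 0L) {
        if (v %in% sig) return(TRUE)
        v <- parent[v]
      }
      FALSE
    }, logical(1))
    keep <- sig[!has_sig_anc]
  }

  desc <- descendant_tips(tree)
  inside_idx <- sort(unique(unlist(lapply(keep, function(v) desc[[v - n]]))))
  structure(list(
    nodes = keep,
    inside = tree$tip.label[inside_idx],
    outside = setdiff(tree$tip.label, tree$tip.label[inside_idx])
  ), class = "hotnode_set")
}

#' @export
print.hotnode_set <- function(x, ...) {
  cat(sprintf("hotnode set: %d maximal clade(s), %d tips inside, %d outside\n",
              length(x$nodes), length(x$inside), length(x$outside)))
  invisible(x)
}
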