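#' Make a tree ultrametric by mean-path-length smoothing
#'
#' Assigns each node an age equal to the mean path length from that node to
#' its descendant tips (tips have age 0), clamps parent ages so they always
#' exceed the oldest child by at least `epsilon`, and rewrites each branch
#' length as `age(parent) - age(child)`.  The result is exactly ultrametric
#' (all root-to-tip paths telescope to the root age), preserves topology and
#' the tip set, and is fully deterministic — no rate model or optimisation
#' is involved, which is all the downstream relative-distance metrics
#' require.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @param epsilon Minimum parent-child age gap used when clamping; default
#'   is `1e-8` times the root age (0 for degenerate inputs never reached,
#'   since zero-depth trees are rejected).
#' @return An ultrametric `"phylo"` tree.
#' @examples
#' tr <- make_ultrametric(read_newick("(A:1,B:3);"))
#' tr$edge.length  # both pendant branches become 2
#' @export
make_ultrametric <- function(tree, epsilon = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  eo <- ape::reorder.phylo(tree, "postorder")

  # mean path length from each node down to its descendant tips
  tip_sum <- numeric(n + m)
  tip_count <- c(rep(1, n), rep(0, m))
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]; len <- eo$edge.length[k]
    tip_sum[p] <- tip_sum[p] + tip_sum[ch] + tip_count[ch] * len
    tip_count[p] <- tip_count[p] + tip_count[ch]
  }
  age <- numeric(n + m)
  internal <- (n + 1):(n + m)
  age[internal] <- tip_sum[internal] / tip_count[internal]
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  if (age[root] <= 0)
    stop("tree has zero depth (all branch lengths 0); cannot ultrametricize")
  if (is.null(epsilon)) epsilon <- 1e-8 * age[root]

  # clamp so every parent is older than its children
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    if (age[p] < age[ch] + epsilon) age[p] <- age[ch] + epsilon
  }

  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  out
}
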