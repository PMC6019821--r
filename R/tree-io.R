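#' Read a rooted phylogeny from a newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the pipeline relies on: unique tip labels, and branch lengths
#' present on every edge.  Trees written without branch lengths (e.g.
#' `"(A,B,C);"`) are accepted, but every edge length is set to 0 and a
#' warning is emitted, since downstream distance metrics are meaningless
#' on such trees.
#'
#' @param text A newick string (with trailing `;`).  Mutually exclusive
#'   with `file`.
#' @param file Path to a newick file.
#' @return An object of class `"phylo"` with an `edge.length` component.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tree <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick parse error: input could not be read as a single tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all edge lengths set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(file)) ape::write.tree(tree) else invisible(ape::write.tree(tree, file = file))
}

#' Patristic (branch-length path) distance matrix
#'
#' Entry `(i, j)` is the sum of branch lengths along the path between tips
#' `i` and `j`.  Rows and columns follow the tree's tip-label order.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to
#'   the tip labels.
#' @examples
#' dm <- patristic_matrix(read_newick("((A:1,B:1):1,C:2);"))
#' dm["A", "C"]  # 4
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  dm <- ape::cophenetic.phylo(tree)
  dm[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Test whether a rooted tree is ultrametric
#'
#' Compares root-to-tip path lengths directly (absolute spread relative to
#' tree depth), which is stricter and more transparent than correlation-based
#' checks.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param tol Maximum allowed spread of root-to-tip distances, as a fraction
#'   of tree depth (absolute when depth is 0).
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  depths <- root_to_tip_depths(tree)
  spread <- max(depths) - min(depths)
  scale <- max(depths)
  if (scale == 0) return(TRUE)
  spread <= tol * scale
}

#' Root-to-tip path lengths
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Named numeric vector, one entry per tip.
#' @export
root_to_tip_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Extract genus names from tip labels
#'
#' Tip labels are assumed to follow the `Genus_species` convention; the
#' genus is the prefix before the first separator.  Labels without the
#' separator are treated as genus-level tips (the whole label is the genus).
#'
#' @param labels Character vector of tip labels.
#' @param sep Separator between genus and epithet (default `"_"`).
#' @return Character vector of genus names.
#' @export
tip_genus <- function(labels, sep = "_") {
  sub(paste0("\\Q", sep, "\\E.*$"), "", labels, perl = TRUE)
}
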