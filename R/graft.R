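#' Graft unsampled species onto a genus-level backbone tree
#'
#' Adds each species in `assignments` as a new tip within its genus,
#' mirroring the manual-polytomy approach used to expand genus-level
#' backbones to species level:
#'
#' * **Polytypic genus** (two or more tips already present): the species is
#'   attached at the genus MRCA, with pendant branch length equal to the
#'   mean path length from that node down to its descendant tips (its
#'   height above the tips).  On an ultrametric tree this preserves
#'   ultrametricity exactly and turns the MRCA into a polytomy.
#' * **Monotypic genus** (a single tip): a new node is created on the
#'   terminal branch at `split_fraction` of its length measured from the
#'   tip, and the species is attached there with a matching pendant
#'   length, so both tips end at the same depth.
#'
#' Species are grafted in order, so a second species added to an initially
#' monotypic genus attaches at the node created for the first.  Existing
#' pairwise tip distances are never altered.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param assignments A data frame with columns `species` and `genus`, or a
#'   named character vector `species -> genus`.
#' @param split_fraction Position of the new node on a monotypic genus's
#'   terminal branch, as a fraction of the branch measured from the tip.
#'   Must be in (0, 1).  Default 0.5.
#' @param sep Separator used to extract genus names from tip labels.
#' @return The expanded `"phylo"` tree with
#'   `Ntip(tree) + nrow(assignments)` tips.
#' @examples
#' tr <- read_newick("((G1_a:1,G1_b:1):1,G2_c:2);")
#' tr2 <- graft_species(tr, data.frame(species = "G1_x", genus = "G1"))
#' ape::Ntip(tr2)  # 4
#' @export
graft_species <- function(tree, assignments, split_fraction = 0.5, sep = "_") {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!(is.numeric(split_fraction) && length(split_fraction) == 1 &&
        split_fraction > 0 && split_fraction < 1))
    stop("`split_fraction` must be a single number in (0, 1)")
  assignments <- as_assignment_df(assignments)
  if (nrow(assignments) == 0L) return(tree)
  if (anyDuplicated(assignments$species))
    stop("duplicate species in assignments")
  if (any(assignments$species %in% tree$tip.label))
    stop("species already present in tree: ",
         paste(intersect(assignments$species, tree$tip.label), collapse = ", "))

  known_genera <- unique(tip_genus(tree$tip.label, sep))
  unknown <- setdiff(unique(assignments$genus), known_genera)
  if (length(unknown))
    stop("unknown genera (no matching tips): ", paste(unknown, collapse = ", "))

  warned <- character(0)
  for (i in seq_len(nrow(assignments))) {
    sp <- assignments$species[i]
    gen <- assignments$genus[i]
    genus_tips <- which(tip_genus(tree$tip.label, sep) == gen)
    if (length(genus_tips) >= 2L) {
      mrca <- ape::getMRCA(tree, genus_tips)
      clade_tips <- descendant_tips(tree)[[mrca - ape::Ntip(tree)]]
      if (length(clade_tips) > length(genus_tips) && !(gen %in% warned)) {
        warning("genus ", gen, " is not monophyletic; attaching at its MRCA")
        warned <- c(warned, gen)
      }
      depths <- ape::node.depth.edgelength(tree)
      pendant <- mean(depths[clade_tips]) - depths[mrca]
      tree <- add_tip_at_node(tree, sp, mrca, pendant)
    } else {
      tip <- genus_tips[1L]
      term_edge <- which(tree$edge[, 2] == tip)
      len <- tree$edge.length[term_edge]
      if (len <= 0)
        stop("cannot split the zero-length terminal branch of ", tree$tip.label[tip])
      pos <- split_fraction * len
      tree <- add_tip_on_terminal_edge(tree, sp, tip, pos, pos)
    }
  }
  tree
}

as_assignment_df <- function(assignments) {
  if (is.data.frame(assignments)) {
    if (!all(c("species", "genus") %in% names(assignments)))
      stop("assignments must have columns `species` and `genus`")
    data.frame(species = as.character(assignments$species),
               genus = as.character(assignments$genus),
               stringsAsFactors = FALSE)
  } else if (is.character(assignments) && !is.null(names(assignments))) {
    data.frame(species = names(assignments), genus = unname(assignments),
               stringsAsFactors = FALSE)
  } else {
    stop("assignments must be a data frame or a named character vector")
  }
}

#' Read a species-to-genus assignment table
#'
#' @param path CSV file with columns `species` and `genus`.
#' @return A data frame suitable for [graft_species()].
#' @export
read_assignments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_assignment_df(df)
}

# Exact edge-matrix surgery for tip insertion.  Done in-package (rather
# than via text round-trips) so grafting preserves existing branch
# lengths bit-for-bit.

# Attach a new pendant tip directly at an existing internal node
# (creating or widening a polytomy).
add_tip_at_node <- function(tree, label, node, pendant) {
  n <- ape::Ntip(tree)
  edge <- tree$edge
  edge[edge > n] <- edge[edge > n] + 1L   # make room for tip id n+1
  edge <- rbind(edge, c(node + 1L, n + 1L))
  rebuild_phylo(edge, c(tree$edge.length, pendant),
                c(tree$tip.label, label), tree$Nnode)
}

# Insert a new node on the terminal branch above `tip`, `position` from
# the tip, and hang the new tip from it with branch length `pendant`.
add_tip_on_terminal_edge <- function(tree, label, tip, position, pendant) {
  n <- ape::Ntip(tree)
  edge <- tree$edge
  elen <- tree$edge.length
  edge[edge > n] <- edge[edge > n] + 1L
  new_node <- max(edge) + 1L
  k <- which(edge[, 2] == tip)
  stopifnot(length(k) == 1L, position < elen[k])
  edge[k, 2] <- new_node
  old_len <- elen[k]
  elen[k] <- old_len - position
  edge <- rbind(edge, c(new_node, tip), c(new_node, n + 1L))
  rebuild_phylo(edge, c(elen, position, pendant),
                c(tree$tip.label, label), tree$Nnode + 1L)
}

# Renumber internal nodes to ape's convention (tips 1..n, root n+1,
# internals in preorder) and return a cladewise "phylo".
rebuild_phylo <- function(edge, elen, labels, nnode) {
  n <- length(labels)
  root <- setdiff(edge[, 1], edge[, 2])
  map <- integer(max(edge))
  map[seq_len(n)] <- seq_len(n)
  children <- split(edge[, 2], edge[, 1])
  nxt <- n + 1L
  stack <- root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    map[v] <- nxt; nxt <- nxt + 1L
    kids <- children[[as.character(v)]]
    stack <- c(kids[kids > n], stack)
  }
  out <- list(edge = cbind(map[edge[, 1]], map[edge[, 2]], deparse.level = 0),
              edge.length = elen, tip.label = labels, Nnode = as.integer(nnode))
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

# Tip indices below each internal node, indexed node - Ntip.
# Computed by postorder accumulation over the edge matrix so node-numbering
# assumptions never enter.
descendant_tips <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  below <- vector("list", n + m)
  for (i in seq_len(n)) below[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply((n + 1):(n + m), function(v) sort(below[[v]]))
}
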