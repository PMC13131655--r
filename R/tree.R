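#' Dated species tree
#'
#' Wraps an `ape::phylo` tree whose branch lengths are durations in million
#' years (MY) into a `dated_tree`: leaf ages are anchored at 0 MYA (the
#' deepest leaf when the tree is not ultrametric) and every branch gets a
#' stable `branch_id` — the child node's label, or for unlabelled internal
#' nodes the concatenation of its sorted descendant tip labels.
#'
#' @param phy An `ape::phylo` object with branch lengths in MY.
#' @return A `dated_tree`: list with `phy`, `root_age` (MYA) and a tibble
#'   `branches` (`branch_id`, `parent_age`, `child_age`, `duration`).
#' @examples
#' dated_tree(ape::read.tree(text = "((A:1,B:1):2,C:3);"))
#' @export
dated_tree <- function(phy) {
  if (!inherits(phy, "phylo")) abort("`phy` must be an ape phylo tree")
  if (is.null(phy$edge.length)) abort("tree has no branch lengths")
  if (any(phy$edge.length <= 0)) abort("zero- or negative-length branch")
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth)
  age <- root_age - depth
  labs <- node_labels(phy)
  br <- tibble(
    branch_id = labs[phy$edge[, 2]],
    parent_age = age[phy$edge[, 1]],
    child_age = age[phy$edge[, 2]],
    duration = phy$edge.length
  )
  if (anyDuplicated(br$branch_id)) abort("branch ids are not unique")
  structure(list(phy = phy, root_age = root_age, branches = br),
            class = "dated_tree")
}

# stable names for all nodes: tip labels; internal node labels when present,
# otherwise sorted concatenated descendant tips
node_labels <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labs <- c(phy$tip.label, rep(NA_character_, nnode))
  tipsets <- c(as.list(phy$tip.label), vector("list", nnode))
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  for (i in seq_len(nnode)) {
    nl <- phy$node.label[i]
    labs[ntip + i] <- if (!is.null(phy$node.label) && !is.na(nl) && nzchar(nl)) {
      nl
    } else {
      paste(sort(tipsets[[ntip + i]]), collapse = "")
    }
  }
  labs
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("<dated_tree> ", length(x$phy$tip.label), " tips, root age ",
      round(x$root_age, 3), " MYA\n", sep = "")
  invisible(x)
}

#' @rdname dated_tree
#' @param path Newick file with branch lengths in MY.
#' @export
read_dated_tree <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  dated_tree(ape::read.tree(path))
}

#' @rdname dated_tree
#' @param tree A `dated_tree`.
#' @export
write_dated_tree <- function(tree, path) {
  ape::write.tree(tree$phy, file = path)
  invisible(path)
}

# branch ids on the root-to-leaf path, root-most first
root_to_leaf_branches <- function(tree, leaf) {
  phy <- tree$phy
  i <- match(leaf, phy$tip.label)
  if (is.na(i)) abort(paste0("leaf '", leaf, "' not in tree"))
  labs <- node_labels(phy)
  path <- character(0)
  node <- i
  root <- length(phy$tip.label) + 1L
  while (node != root) {
    path <- c(labs[node], path)
    node <- phy$edge[match(node, phy$edge[, 2]), 1]
  }
  path
}
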