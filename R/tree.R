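#' Read a rooted phylogeny from Newick
#'
#' Thin wrapper around [ape::read.tree()] that validates leaf-label
#' uniqueness and strips any branch lengths: the optimization derives branch
#' lengths from landmark displacement, it never consumes them (a notice is
#' emitted when input lengths are dropped). Polytomies are accepted.
#'
#' @param file Path to a Newick file, or content via `text`.
#' @param text Optional Newick string.
#' @return An [ape::phylo] tree (topology only).
#' @export
read_newick_tree <- function(file = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (is.null(file)) abort("supply `file` or `text`")
    ape::read.tree(file)
  }
  if (is.null(tr)) abort("malformed Newick string")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("duplicate leaf labels: ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")))
  }
  if (!is.null(tr$edge.length)) {
    inform("input branch lengths ignored (topology-only analysis)")
    tr$edge.length <- NULL
  }
  tr
}

# tip labels subtended by `node` (tip or internal)
subtended_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Find the branch subtending exactly a given clade
#'
#' Identifies the branch (by its child node) whose subtended leaf set equals
#' `clade_leaves` — e.g. the Erythrosuchidae + Eucrocopoda stem branch.
#' Errors if the set is not monophyletic in this tree, or if it spans all
#' leaves (the root has no stem branch).
#'
#' @param tree An [ape::phylo] tree.
#' @param clade_leaves Character vector of leaf labels.
#' @return The child-node id (integer) identifying the branch.
#' @export
find_branch <- function(tree, clade_leaves) {
  clade_leaves <- unique(as.character(clade_leaves))
  unknown <- setdiff(clade_leaves, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("leaves not in tree: ", paste(unknown, collapse = ", ")))
  }
  if (length(clade_leaves) == length(tree$tip.label)) {
    abort("clade equals the full leaf set: the root has no stem branch")
  }
  node <- if (length(clade_leaves) == 1) {
    match(clade_leaves, tree$tip.label)
  } else {
    ape::getMRCA(tree, clade_leaves)
  }
  found <- subtended_tips(tree, node)
  if (!setequal(found, clade_leaves)) {
    extra <- setdiff(found, clade_leaves)
    abort(paste0("clade not monophyletic here: its MRCA also subtends ",
                 paste(extra, collapse = ", ")))
  }
  as.integer(node)
}

#' Leaves subtended by a branch
#'
#' Inverse of [find_branch()]: lists the leaf labels below the branch
#' identified by its child node.
#'
#' @param tree An [ape::phylo] tree.
#' @param branch Child-node id.
#' @return Character vector of leaf labels.
#' @export
branch_leaves <- function(tree, branch) {
  n_node <- length(tree$tip.label) + tree$Nnode
  if (branch < 1 || branch > n_node) abort("invalid branch id")
  subtended_tips(tree, branch)
}
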