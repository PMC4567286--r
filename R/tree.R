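#' Read a rooted phylogeny from a newick file
#'
#' @param path Path to a newick file. The tree must be rooted, carry branch
#'   lengths, and have non-negative edge lengths; leaf labels are the OTU
#'   identifiers used by UniFrac and Faith's PD.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylo_tree <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("tree file not found: ", path))
  }
  tree <- ape::read.tree(path)
  if (is.null(tree)) {
    abort(paste0("could not parse newick tree from: ", path))
  }
  validate_phylo_tree(tree)
}

#' Validate a phylogeny for use in phylogenetic diversity computations
#'
#' @param tree A `phylo` object.
#' @return The tree, unchanged, for use in a pipe.
#' @export
validate_phylo_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    abort("tree must be a 'phylo' object")
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    abort("tree has negative branch lengths")
  }
  if (!ape::is.rooted(tree)) {
    abort("tree must be rooted")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicated leaf label: ",
                 tree$tip.label[duplicated(tree$tip.label)][[1]]))
  }
  tree
}

# Error (listing ids) unless every id is a leaf of the tree.
check_leaves <- function(ids, tree, what = "OTU") {
  missing <- setdiff(ids, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0(what, " id(s) absent from the tree: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) paste0(" (and ", length(missing) - 10, " more)") else ""))
  }
  invisible(ids)
}
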