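#' Read a rooted binary phylogeny from Newick
#'
#' Thin validating wrapper around [ape::read.tree()].  The tree must be
#' rooted, strictly binary (the root has exactly two children, no
#' polytomies) and carry a branch length on every edge; anything else is
#' rejected with an explanatory error.  Branches are addressed
#' throughout the package by the ape index of their child node, which is
#' stable under [write_newick()] round-trips.
#'
#' @param text Newick string, or a file path if `file` is used instead.
#' @param file Optional path to a Newick file.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  tr <- if (!is.null(file)) ape::read.tree(file = file)
        else ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input", call. = FALSE)
  validate_phylogeny(tr)
}

validate_phylogeny <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("every branch must carry a branch length", call. = FALSE)
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  if (!ape::is.rooted(tr))
    stop("an explicitly rooted tree is required", call. = FALSE)
  if (!ape::is.binary(tr))
    stop("polytomies are not supported; resolve the tree first",
         call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicated tip labels", call. = FALSE)
  n <- length(tr$tip.label)
  if (nrow(tr$edge) != 2L * n - 2L)
    stop("unexpected edge count for a rooted binary tree", call. = FALSE)
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root-ward time depth of a node
#'
#' Age of a node measured against the deepest tip: the maximum
#' root-to-leaf path length minus the root-to-node path length.  On an
#' ultrametric tree this is the usual node age (0 at every tip); on
#' non-ultrametric trees the convention anchors age 0 at the most
#' distant tip.
#'
#' @param tree A `phylo` object.
#' @param node Node index (ape numbering); vectorised.
#' @return Numeric vector of time depths.
#' @export
node_time_depth <- function(tree, node) {
  d <- ape::node.depth.edgelength(tree)   # root-to-node distances
  n_tip <- length(tree$tip.label)
  max(d[seq_len(n_tip)]) - d[node]
}

# branch id = child node index; rows of tree$edge in input order
branch_ids <- function(tree) tree$edge[, 2]
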