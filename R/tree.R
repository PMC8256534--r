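#' Read a rooted phylogenetic tree from a newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream null
#' models rely on: every edge must carry an explicit non-negative branch
#' length (no default length is invented for missing ones, since
#' patristic distances are the substance of the analysis) and tip labels
#' must be unique. Polytomies, including basal ones (star trees), are
#' allowed; zero-length branches are allowed, negative ones are not.
#'
#' @param path newick file path (or use `text`).
#' @param text optional newick string, as in [ape::read.tree()].
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    ape::read.tree(path)
  } else ape::read.tree(text = text)
  if (is.null(tr)) stopf("could not parse newick input")
  validate_tree(tr)
  tr
}

#' Validate a phylogenetic tree for use in the pipeline
#'
#' @param tree an [ape::phylo] object.
#' @param ultrametric if `TRUE`, additionally require all root-to-tip
#'   distances to be equal (relative tolerance `1e-6`).
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree, ultrametric = FALSE) {
  if (!inherits(tree, "phylo")) stopf("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stopf("tree parse error: every edge must have an explicit branch length")
  if (any(tree$edge.length < 0))
    stopf("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (ultrametric && !ape::is.ultrametric(tree, option = 2, tol = 1e-6))
    stopf("tree is not ultrametric within 1e-6 relative tolerance")
  invisible(tree)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return symmetric taxa-x-taxa matrix with zero diagonal, rows/columns
#'   named by tip label.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  stats::cophenetic(tree)
}
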