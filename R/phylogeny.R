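#' Read and validate a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the structure the
#' downstream models require: unique tip labels, branch lengths present and
#' non-negative. Unlabelled internal nodes are tolerated.
#'
#' @param path Path to a Newick file. Ignored when `text` is given.
#' @param text Optional Newick string, as in [ape::read.tree()].
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  if (anyDuplicated(tr$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("tree must carry branch lengths on every edge")
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed")
  invisible(tr)
}

#' Prune a tree to a set of species
#'
#' Returns the induced subtree on `species`, with degree-2 nodes collapsed
#' and their branch lengths summed. Any basal path between the original
#' root and the new root is retained as the tree's `root.edge`, so
#' root-to-tip depths — and hence the shared-path covariance — are
#' preserved exactly (the pruned covariance is the submatrix of the full
#' one).
#'
#' @param tree A `phylo` tree.
#' @param species Character vector, a subset of `tree$tip.label`.
#' @return A `phylo` tree with tips `species`.
#' @export
prune_to <- function(tree, species) {
  validate_tree(tree)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stop("species not in the tree: ", paste(unknown, collapse = ", "))
  if (length(species) < 2L) stop("need at least two species to keep")
  pruned <- ape::drop.tip(tree, setdiff(tree$tip.label, species))
  # depth lost when the root moves down to the MRCA of the kept species,
  # plus any pre-existing root edge
  ref <- species[1L]
  d_old <- ape::node.depth.edgelength(tree)[match(ref, tree$tip.label)]
  d_new <- ape::node.depth.edgelength(pruned)[match(ref, pruned$tip.label)]
  stem <- d_old - d_new
  if (!is.null(tree$root.edge)) stem <- stem + tree$root.edge
  if (stem > 1e-12) pruned$root.edge <- stem
  pruned
}

#' Brownian-motion phylogenetic covariance from a tree
#'
#' Under a Brownian trait model the covariance between two tips equals the
#' length of the root-to-tip path they share. `normalize = TRUE` rescales to
#' a correlation matrix (entry divided by the geometric mean of the two
#' diagonals), which is what the regression models consume so that the
#' phylogenetic standard deviation is identifiable and comparable across
#' trees. Non-ultrametric trees are accepted with a warning.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param normalize Return the correlation (unit-diagonal) form.
#' @return Square numeric matrix ordered and labelled by `tree$tip.label`,
#'   with attribute `normalized`.
#' @export
phylo_vcv <- function(tree, normalize = TRUE) {
  validate_tree(tree)
  V <- ape::vcv(tree)
  V <- V[tree$tip.label, tree$tip.label]
  # a retained root edge (e.g. after pruning) is shared by every tip pair
  if (!is.null(tree$root.edge)) V <- V + tree$root.edge
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    warning("tree is not ultrametric; diagonal entries are unequal ",
            "root-to-tip depths")
  if (normalize) V <- stats::cov2cor(V)
  attr(V, "normalized") <- normalize
  V
}

#' Write a covariance/correlation matrix as CSV with tip labels
#'
#' @param V Matrix from [phylo_vcv()].
#' @param path Output file path.
#' @export
write_vcv_csv <- function(V, path) {
  utils::write.csv(as.data.frame(V), path, row.names = TRUE)
  invisible(path)
}
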