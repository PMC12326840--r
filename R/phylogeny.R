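## Time-calibrated phylogeny handling. Trees are `ape::phylo` objects
## validated for ultrametricity; all divergence/shared-time bookkeeping
## needed by the OU machinery lives here.

#' Read and validate an ultrametric time tree
#'
#' Parses a Newick file with branch lengths in millions of years (Myr) and
#' validates that the tree is ultrametric: every root-to-tip path length must
#' agree within `tol` (relative to tree height). All cross-species analyses
#' assume a time-calibrated tree, so non-ultrametric input is an error, not a
#' warning.
#'
#' @param path Path to a Newick file with branch lengths.
#' @param tol Relative ultrametricity tolerance (default `1e-6`): maximum
#'   allowed deviation of any root-to-tip path from the tree height, as a
#'   fraction of the height.
#' @return An object of class `phylo` (see [ape::read.tree()]) that has
#'   passed [validate_phylogeny()].
#' @seealso [divergence_matrix()], [shared_time_matrix()], [tree_height()]
#' @export
read_newick <- function(path, tol = 1e-6) {
  assert_that(file.exists(path), sprintf("tree file not found: %s", path))
  tree <- ape::read.tree(path)
  assert_that(inherits(tree, "phylo"),
              sprintf("could not parse a Newick tree from %s", path))
  validate_phylogeny(tree, tol = tol)
}

#' Validate a phylogeny for use in conservation analyses
#'
#' Checks that branch lengths are present and non-negative, tip labels are
#' unique, and the tree is ultrametric within `tol`. On failure the error
#' names the offending tip.
#'
#' @param tree A `phylo` object.
#' @inheritParams read_newick
#' @return The tree, invisibly unchanged, on success.
#' @export
validate_phylogeny <- function(tree, tol = 1e-6) {
  assert_that(inherits(tree, "phylo"), "not a 'phylo' object")
  assert_that(!is.null(tree$edge.length), "tree has no branch lengths")
  assert_that(all(is.finite(tree$edge.length)) && all(tree$edge.length >= 0),
              "tree has missing or negative branch lengths")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  assert_that(length(dup) == 0L,
              sprintf("duplicated tip labels: %s", paste(dup, collapse = ", ")))
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  assert_that(h > 0, "tree height is zero")
  dev <- abs(depths - h) / h
  if (any(dev > tol)) {
    worst <- which.max(dev)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' has root-to-tip length %.6g vs height %.6g",
      tree$tip.label[worst], depths[worst], h), call. = FALSE)
  }
  tree
}

#' Tree height (root-to-tip time)
#'
#' @param tree A validated ultrametric `phylo`.
#' @return Root-to-tip time in the tree's branch-length units (Myr).
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Shared-ancestry time matrix
#'
#' For an ultrametric tree, entry (i, j) is the time from the root to the most
#' recent common ancestor of tips i and j; the diagonal equals the tree
#' height. This is the Brownian-motion covariance structure of the tree (up to
#' the rate constant).
#'
#' @inheritParams tree_height
#' @return A symmetric matrix with tip labels as dimnames, in Myr.
#' @export
shared_time_matrix <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Pairwise divergence-time matrix
#'
#' Entry (i, j) is the time since the split of tips i and j: half the patristic
#' (path) distance on an ultrametric tree. Symmetric with a zero diagonal.
#'
#' @inheritParams tree_height
#' @return A symmetric matrix of divergence times in Myr.
#' @export
divergence_matrix <- function(tree) {
  s <- shared_time_matrix(tree)
  depths <- diag(s)
  d <- (outer(depths, rep(1, length(depths))) +
          outer(rep(1, length(depths)), depths)) / 2 - s
  ## on an ultrametric tree depths are all equal, so d = height - s
  dimnames(d) <- dimnames(s)
  d
}

#' Synthetic mammal-like time tree
#'
#' A fixed, deterministic 10-tip ultrametric phylogeny with round-number
#' divergence times in the TimeTree style (human-chimp 6 Myr, mouse-rat 13,
#' cat-dog 55, primates-glires 90, root 100 Myr). It is a synthetic fixture
#' shaped like the boreoeutherian mammal clade — the nested mix of shallow
#' and deep splits that comparative TAD analyses operate on — not a
#' literature-calibrated tree.
#'
#' @return A validated ultrametric `phylo` of height 100 Myr.
#' @export
mammal_tree <- function() {
  txt <- paste0(
    "((((human:6,chimp:6):24,rhesus:30):60,",
    "((mouse:13,rat:13):67,rabbit:80):10):10,",
    "((cat:55,dog:55):23,(cow:62,pig:62):16):22);")
  validate_phylogeny(ape::read.tree(text = txt))
}

#' Divergence time between two species
#'
#' @inheritParams tree_height
#' @param species_i,species_j Tip labels.
#' @return Time since split in Myr.
#' @export
divergence_time <- function(tree, species_i, species_j) {
  d <- divergence_matrix(tree)
  assert_that(all(c(species_i, species_j) %in% rownames(d)),
              "species not found in tree")
  d[species_i, species_j]
}
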