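#' Simulate an ultrametric chronogram
#'
#' Generates a rooted binary ultrametric tree with a fixed number of tips
#' under a birth-death process conditioned on the number of extant taxa, then
#' rescales all branch durations so that the root age equals `root_age`. The
#' tree stands in for an empirically derived chronogram; user-supplied Newick
#' chronograms can be substituted via [load_chronogram()].
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate per Myr (only the birth/death ratio
#'   affects tree shape after rescaling to `root_age`).
#' @param death_rate Extinction rate per Myr, `0 <= death_rate < birth_rate`.
#' @param root_age Root age in Myr; defaults to 139.40, the depth of the
#'   angiosperm chronograms that motivate the package defaults.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `phylo`: rooted, binary, ultrametric, with
#'   branch lengths in Myr.
#' @export
#' @examples
#' tr <- simulate_chronogram(18, seed = 1)
#' max(node_ages(tr))
simulate_chronogram <- function(n_taxa, birth_rate = 0.1, death_rate = 0.05,
                                root_age = 139.40, seed = NULL) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 2)
    stop("`n_taxa` must be a single integer >= 2")
  if (root_age <= 0) stop("`root_age` must be positive")
  if (!(birth_rate > death_rate) || death_rate < 0)
    stop("need birth_rate > death_rate >= 0")
  n_taxa <- as.integer(n_taxa)
  tr <- if (n_taxa == 2L) {
    ape::read.tree(text = sprintf("(t1:%.10g,t2:%.10g);", root_age, root_age))
  } else {
    t0 <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate,
                                      death = death_rate, fossils = FALSE))
    depth <- max(ape::node.depth.edgelength(t0))
    t0$edge.length <- t0$edge.length * (root_age / depth)
    t0
  }
  assert_chronogram(tr)
  tr
}

#' Read and validate a chronogram from Newick
#'
#' Parses Newick text (or a file) with [ape::read.tree()] and checks the
#' chronogram invariants: rooted binary topology, strictly positive branch
#' durations, and ultrametricity within a relative tolerance. Non-ultrametric
#' input triggers an error that names the most deviant tip.
#'
#' @param newick Newick string (must contain branch lengths), or a file path
#'   when `file = TRUE`.
#' @param file Logical; treat `newick` as a path.
#' @param tol Relative tolerance for root-to-tip path-sum equality.
#' @return A validated `phylo` chronogram.
#' @export
#' @examples
#' load_chronogram("(A:1,B:1);")
load_chronogram <- function(newick, file = FALSE, tol = 1e-6) {
  tr <- if (file) ape::read.tree(newick) else ape::read.tree(text = newick)
  if (is.null(tr)) stop("could not parse Newick input")
  if (is.null(tr$edge.length)) stop("Newick input has no branch lengths")
  assert_chronogram(tr, tol = tol)
  tr
}

#' Write a tree to a Newick string or file
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Node ages of an ultrametric tree
#'
#' @param tree A `phylo` chronogram.
#' @return Numeric vector of ages (Myr, tips at ~0) indexed by node number
#'   (tips `1..n`, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Validate chronogram invariants
#'
#' Checks that a tree is rooted, binary, has strictly positive branch
#' durations, and is ultrametric (all root-to-tip path sums equal within a
#' relative tolerance). Called internally by every chronogram-producing
#' operation.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on root-to-tip path sums.
#' @return `tree`, invisibly.
#' @export
assert_chronogram <- function(tree, tol = 1e-9) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  n <- ape::Ntip(tree)
  if (!ape::is.rooted(tree)) stop("chronogram must be rooted")
  if (!ape::is.binary(tree)) stop("chronogram must be binary")
  if (nrow(tree$edge) != 2L * n - 2L)
    stop("rooted binary tree must have 2n-2 branches")
  if (any(tree$edge.length <= 0))
    stop("all branch durations must be positive")
  depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
  age <- max(depth)
  rel <- abs(depth - age) / age
  if (any(rel > tol)) {
    worst <- which.max(rel)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' has root-to-tip length %.9g vs root age %.9g",
      tree$tip.label[worst], depth[worst], age))
  }
  invisible(tree)
}

# Map of tree edges to their child-node labels; used to key per-branch rates.
edge_ids <- function(tree) {
  ch <- tree$edge[, 2L]
  n <- ape::Ntip(tree)
  ifelse(ch <= n, tree$tip.label[ch], paste0("node", ch))
}
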