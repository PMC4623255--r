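#' Sample an ultrametric species tree
#'
#' Draws a rooted binary tree under a pure-birth (Yule) process and rescales
#' the branch lengths so that every root-to-tip path equals `total_depth`
#' expected substitutions per site. Stands in for the organismal phylogeny
#' along which backbone genomes evolve.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param total_depth Root-to-tip path length in expected substitutions per
#'   site (>= 0).
#' @param seed Integer seed; sampling is fully deterministic given the seed.
#' @param labels Optional leaf labels (defaults to `g1..gn`).
#' @return An [ape::phylo] tree, ultrametric, with `n_taxa` leaves.
#' @export
sample_species_tree <- function(n_taxa, total_depth, seed, labels = NULL) {
  if (!is.numeric(n_taxa) || n_taxa < 2) abort("n_taxa must be >= 2")
  if (total_depth < 0) abort("total_depth must be >= 0")
  n_taxa <- as.integer(n_taxa)
  tr <- if (n_taxa == 2) {
    ape::read.tree(text = sprintf("(g1:%.10f,g2:%.10f);", total_depth, total_depth))
  } else {
    tr <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0, fossils = FALSE))
    depth <- max(ape::node.depth.edgelength(tr)[seq_len(n_taxa)])
    tr$edge.length <- if (depth > 0) tr$edge.length * (total_depth / depth) else tr$edge.length * 0
    tr$tip.label <- paste0("g", seq_len(n_taxa))
    tr
  }
  tr
}

#' Root-to-tip path lengths of a tree
#' @param tree An [ape::phylo] tree.
#' @return Named numeric vector over leaves.
#' @export
root_to_tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  stats::setNames(d, tree$tip.label)
}
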