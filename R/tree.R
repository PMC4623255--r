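#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via [ape::nj]). Negative branch lengths --
#' an NJ artefact on noisy distances -- are clamped to zero with the
#' deficit transferred to the sister edge, preserving path lengths through
#' the parent node.
#'
#' @param dm Symmetric distance matrix (taxa in dimnames), e.g. from
#'   [poisson_distance_matrix()].
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3) abort("need at least 3 taxa for a tree")
  tr <- ape::nj(stats::as.dist(dm))
  clamp_negative_branches(tr)
}

clamp_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sisters <- which(tr$edge[, 1] == tr$edge[e, 1])
    sisters <- setdiff(sisters, e)
    if (length(sisters)) {
      s <- sisters[1]
      tr$edge.length[s] <- tr$edge.length[s] + deficit
      if (tr$edge.length[s] < 0) tr$edge.length[s] <- 0
    }
  }
  tr
}

#' Bootstrap support values for a supermatrix NJ tree
#'
#' Resamples supermatrix columns with replacement `n_reps` times, rebuilds
#' the Poisson-distance NJ tree for each replicate, and reports for every
#' internal edge of the full-data tree the percentage of replicate trees
#' containing the same bipartition (branch lengths ignored, supports
#' rounded half-up to integer percent). Supports are stored in
#' `tree$node.label`; edges never recovered get 0.
#'
#' @param sm A `gi_supermatrix`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The full-data NJ tree with `node.label` supports (root label
#'   empty) and a `"replicates"` attribute holding the replicate trees.
#' @export
bootstrap_supports <- function(sm, n_reps, seed) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  main <- nj_tree(poisson_distance_matrix(sm))
  L <- nchar(sm$alignment[[1]])
  rows <- alignment_matrix(sm$alignment)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- rows[, cols, drop = FALSE]
      aln <- new_alignment(apply(res, 1, paste, collapse = ""))
      nj_tree(poisson_distance_matrix(aln))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- floor(100 * counts / n_reps + 0.5)
  support[1] <- NA  # root node of an unrooted tree carries no bipartition
  main$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(main, "replicates") <- reps
  main
}

#' Write a tree with supports as Newick
#' @param tree An [ape::phylo] tree (supports in `node.label` if present).
#' @param path Output path.
#' @export
write_support_tree <- function(tree, path) {
  attr(tree, "replicates") <- NULL
  ape::write.tree(tree, path)
  invisible(path)
}

#' Tidy a support tree into an edge table
#'
#' @param x An [ape::phylo] tree with optional `node.label` supports.
#' @param ... Unused.
#' @return Tibble with one row per edge: `parent`, `child`, `length`,
#'   `child_label` (taxon for pendant edges), `support` (internal edges
#'   only).
#' @export
tidy.phylo <- function(x, ...) {
  n_tip <- length(x$tip.label)
  child <- x$edge[, 2]
  labels <- ifelse(child <= n_tip, x$tip.label[child], NA_character_)
  support <- rep(NA_real_, nrow(x$edge))
  if (!is.null(x$node.label)) {
    internal <- child > n_tip
    sup <- suppressWarnings(as.numeric(x$node.label[child[internal] - n_tip]))
    support[internal] <- sup
  }
  tibble::tibble(
    parent = x$edge[, 1], child = child,
    length = x$edge.length %||% rep(NA_real_, nrow(x$edge)),
    child_label = labels, support = support
  )
}

#' Full MLSA stage: loci to supported tree
#'
#' Aligns each single-copy locus, trims conserved blocks, concatenates,
#' and infers the NJ tree with bootstrap supports.
#'
#' @param locus_seqs Named list of per-locus named character vectors
#'   (taxon -> protein sequence).
#' @param n_reps Bootstrap replicates.
#' @param seed Integer seed.
#' @param trim Apply [conserved_block_filter()] per locus (default TRUE).
#' @return List with `supermatrix`, `tree` (supports attached), and
#'   `alignments`.
#' @export
mlsa_pipeline <- function(locus_seqs, n_reps = 100, seed, trim = TRUE) {
  alns <- lapply(locus_seqs, progressive_align)
  if (trim) alns <- lapply(alns, function(a) conserved_block_filter(a)$alignment)
  alns <- alns[vapply(alns, function(a) nchar(a[[1]]) > 0, logical(1))]
  if (!length(alns)) abort("no columns survive trimming")
  sm <- concatenate_supermatrix(alns)
  tree <- bootstrap_supports(sm, n_reps = n_reps, seed = seed)
  list(supermatrix = sm, tree = tree, alignments = alns)
}
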