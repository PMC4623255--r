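#' Evolve a root genome along a species tree under JC69
#'
#' Substitution-only forward simulation: on every branch of length `t`
#' (expected substitutions per site) the number of substitution events is
#' Poisson(`t * L`), event sites are uniform with replacement (so multiple
#' hits can collide), and each event replaces the current base by one of the
#' three alternatives uniformly. Sequence length, feature coordinates and
#' gene labels are conserved, which is what makes downstream SNP calls
#' checkable base-by-base against the planted history.
#'
#' @param tree An [ape::phylo] tree with branch lengths in expected
#'   substitutions per site.
#' @param root A `gi_genome` used as the ancestral state.
#' @param seed Integer seed.
#' @return A list with `genomes` (named list of leaf `gi_genome`s) and
#'   `events` (tibble of realized substitution events: `branch`, `child`,
#'   `child_label`, `contig`, `site`, `from`, `to`).
#' @export
evolve_sequences <- function(tree, root, seed) {
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0")
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    seqs <- vector("list", n_node)
    root_node <- n_tip + 1L
    seqs[[root_node]] <- root$contigs
    edge <- tree$edge
    # cladewise preorder: parents always visited before children
    edge_order <- reorder_edges_preorder(tree)
    events <- vector("list", nrow(edge))
    for (e in edge_order) {
      parent <- edge[e, 1]; child <- edge[e, 2]
      t_len <- tree$edge.length[e]
      res <- mutate_jc_contigs(seqs[[parent]], t_len)
      seqs[[child]] <- res$contigs
      if (nrow(res$events)) {
        res$events$branch <- e
        res$events$child <- child
        res$events$child_label <- if (child <= n_tip) tree$tip.label[child] else paste0("node_", child)
        events[[e]] <- res$events
      }
    }
    genomes <- lapply(seq_len(n_tip), function(i) {
      g <- root
      g$genome_id <- tree$tip.label[i]
      g$contigs <- seqs[[i]]
      g
    })
    names(genomes) <- tree$tip.label
    ev <- dplyr::bind_rows(events)
    if (!nrow(ev)) {
      ev <- tibble::tibble(
        contig = character(), site = integer(), from = character(),
        to = character(), branch = integer(), child = integer(),
        child_label = character()
      )
    }
    list(genomes = genomes, events = ev[, c("branch", "child", "child_label", "contig", "site", "from", "to")])
  })
}

# edge indices in an order where every parent precedes its children
reorder_edges_preorder <- function(tree) {
  tr <- stats::reorder(tree, order = "cladewise")
  match(paste(tr$edge[, 1], tr$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
}

mutate_jc_contigs <- function(contigs, t_len) {
  evs <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    res <- mutate_jc(contigs[[i]], t_len)
    contigs[[i]] <- res$seq
    if (nrow(res$events)) {
      res$events$contig <- names(contigs)[i]
      evs[[i]] <- res$events
    }
  }
  list(contigs = contigs, events = dplyr::bind_rows(evs))
}

# One JC69 branch on a single sequence; returns the mutated sequence and the
# realized event table (sequential, so multiple hits at a site chain).
mutate_jc <- function(seq, t_len) {
  L <- nchar(seq)
  empty <- tibble::tibble(site = integer(), from = character(), to = character())
  n_ev <- stats::rpois(1, t_len * L)
  if (L == 0 || n_ev == 0) return(list(seq = seq, events = empty))
  sites <- sample.int(L, n_ev, replace = TRUE)
  v <- chars(seq)
  from <- character(n_ev); to <- character(n_ev)
  pick <- sample.int(3, n_ev, replace = TRUE)
  for (j in seq_len(n_ev)) {
    s <- sites[j]
    from[j] <- v[s]
    to[j] <- BASE_ALTERNATIVES[[from[j]]][pick[j]]
    v[s] <- to[j]
  }
  list(seq = paste_chars(v), events = tibble::tibble(site = sites, from = from, to = to))
}

# Mutate a bare sequence by JC69 at distance d (helper for island copies)
mutate_sequence_jc <- function(seq, d, seed) {
  with_seed(seed, mutate_jc(seq, d))
}
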