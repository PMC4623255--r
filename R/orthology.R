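#' Score a local protein alignment
#'
#' Optimal Smith-Waterman local alignment with affine gaps (via
#' `Biostrings::pairwiseAlignment`), the pairwise similarity engine behind
#' ortholog detection. Identity is matches / alignment columns of the
#' optimal traceback, gaps counting as columns.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters; a gap of length g costs
#'   `gap_open + g * gap_extend`.
#' @return One-row tibble: `score`, `identity`, `aln_length`.
#' @export
score_local_alignment <- function(a, b, matrix = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend
  )
  len <- Biostrings::nchar(pa)
  tibble::tibble(
    score = max(0, Biostrings::score(pa)),
    identity = if (len > 0) Biostrings::nmatch(pa) / len else 0,
    aln_length = as.integer(len)
  )
}

#' All-vs-all protein similarity search across proteomes
#'
#' Computes local alignments between every gene pair of every genome pair
#' and keeps hits passing the score and coverage thresholds. The symmetric
#' score is reported in both directions, giving the hit table the
#' reciprocal-best-hit step expects.
#'
#' @param proteins Tibble of proteins as from [proteome()] (columns
#'   `genome_id`, `gene_id`, `seq`), covering two or more genomes.
#' @param min_score Minimum local alignment score.
#' @param min_coverage Minimum alignment length as a fraction of the shorter
#'   sequence.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return Tibble: `query_genome`, `query_id`, `subject_genome`,
#'   `subject_id`, `score`, `identity`, `aln_length`, ordered
#'   deterministically.
#' @export
all_vs_all_hits <- function(proteins, min_score = 50, min_coverage = 0.5,
                            matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  genomes <- sort(unique(proteins$genome_id))
  if (length(genomes) < 2) abort("need proteins from at least two genomes")
  out <- list()
  for (i in seq_along(genomes)) {
    for (j in seq_along(genomes)) {
      if (j <= i) next
      pa <- proteins[proteins$genome_id == genomes[i], ]
      pb <- proteins[proteins$genome_id == genomes[j], ]
      hits <- pairwise_hit_block(pa, pb, min_score, min_coverage, matrix, gap_open, gap_extend)
      if (nrow(hits)) {
        rev <- hits
        names(rev) <- c("subject_genome", "subject_id", "query_genome", "query_id",
                        "score", "identity", "aln_length")
        out[[length(out) + 1]] <- hits
        out[[length(out) + 1]] <- rev[, names(hits)]
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    return(tibble::tibble(
      query_genome = character(), query_id = character(),
      subject_genome = character(), subject_id = character(),
      score = numeric(), identity = numeric(), aln_length = integer()
    ))
  }
  dplyr::arrange(res, .data$query_genome, .data$query_id,
                 .data$subject_genome, .data$subject_id)
}

# one genome pair, vectorised over queries per subject
pairwise_hit_block <- function(pa, pb, min_score, min_coverage,
                               matrix, gap_open, gap_extend) {
  if (!nrow(pa) || !nrow(pb)) return(tibble::tibble())
  qset <- Biostrings::AAStringSet(pa$seq)
  rows <- vector("list", nrow(pb))
  for (k in seq_len(nrow(pb))) {
    aln <- Biostrings::pairwiseAlignment(
      qset, Biostrings::AAString(pb$seq[k]), type = "local",
      substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend
    )
    sc <- Biostrings::score(aln)
    len <- Biostrings::nchar(aln)
    shorter <- pmin(nchar(pa$seq), nchar(pb$seq[k]))
    keep <- sc >= min_score & len >= min_coverage * shorter
    if (any(keep)) {
      rows[[k]] <- tibble::tibble(
        query_genome = pa$genome_id[keep], query_id = pa$gene_id[keep],
        subject_genome = pb$genome_id[k], subject_id = pb$gene_id[k],
        score = sc[keep],
        identity = ifelse(len[keep] > 0, Biostrings::nmatch(aln)[keep] / len[keep], 0),
        aln_length = as.integer(len[keep])
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Reciprocal best hits between two genomes
#'
#' A pair (a, b) is reported iff b is a's unique best-scoring subject in
#' genome B and a is b's unique best-scoring subject in genome A. Score ties
#' for best hit exclude the gene (conservative).
#'
#' @param hits Hit table from [all_vs_all_hits()] (both directions present).
#' @param genome_a,genome_b Genome ids.
#' @return Tibble: `genome_a`, `gene_a`, `genome_b`, `gene_b`, `score`.
#' @export
reciprocal_best_hits <- function(hits, genome_a, genome_b) {
  ab <- hits[hits$query_genome == genome_a & hits$subject_genome == genome_b, ]
  ba <- hits[hits$query_genome == genome_b & hits$subject_genome == genome_a, ]
  best_ab <- unique_best(ab)
  best_ba <- unique_best(ba)
  m <- dplyr::inner_join(
    best_ab, best_ba,
    by = c("query_id" = "subject_id", "subject_id" = "query_id"),
    suffix = c("", ".rev")
  )
  tibble::tibble(
    genome_a = genome_a, gene_a = m$query_id,
    genome_b = genome_b, gene_b = m$subject_id,
    score = m$score
  )
}

# per query, its single best subject; queries with tied best hits dropped
unique_best <- function(tab) {
  if (!nrow(tab)) {
    return(tibble::tibble(query_id = character(), subject_id = character(), score = numeric()))
  }
  tab |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select("query_id", "subject_id", "score")
}

#' Cluster genes by connected components of the RBH graph
#'
#' Nodes are (genome, gene) pairs, edges are reciprocal best hits from every
#' genome pair; clusters are the connected components (transitive closure).
#'
#' @param rbh_pairs Tibble binding the [reciprocal_best_hits()] output for
#'   every genome pair.
#' @return Tibble: `cluster_id`, `genome_id`, `gene_id`; cluster ids are
#'   stable (ordered by first member).
#' @export
cluster_rbh_graph <- function(rbh_pairs) {
  if (!nrow(rbh_pairs)) {
    return(tibble::tibble(cluster_id = character(), genome_id = character(), gene_id = character()))
  }
  key_a <- paste(rbh_pairs$genome_a, rbh_pairs$gene_a, sep = "\r")
  key_b <- paste(rbh_pairs$genome_b, rbh_pairs$gene_b, sep = "\r")
  g <- igraph::graph_from_edgelist(cbind(key_a, key_b), directed = FALSE)
  comp <- igraph::components(g)
  keys <- names(comp$membership)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  res <- tibble::tibble(
    member = comp$membership,
    genome_id = vapply(parts, `[`, character(1), 1),
    gene_id = vapply(parts, `[`, character(1), 2)
  ) |>
    dplyr::arrange(.data$genome_id, .data$gene_id)
  first_seen <- !duplicated(res$member)
  relabel <- stats::setNames(seq_len(sum(first_seen)), res$member[first_seen])
  res$cluster_id <- sprintf("OC%04d", relabel[as.character(res$member)])
  dplyr::arrange(res[, c("cluster_id", "genome_id", "gene_id")],
                 .data$cluster_id, .data$genome_id, .data$gene_id)
}

#' Keep only single-copy-complete ortholog clusters
#'
#' The locus-selection criterion for supermatrix phylogenetics: a cluster is
#' retained iff it has exactly one member in every genome of the evaluation
#' set -- paralog-containing and incomplete clusters are dropped.
#'
#' @param clusters Tibble from [cluster_rbh_graph()].
#' @param genome_set Character vector of genome ids defining completeness.
#' @return Filtered cluster tibble (same schema, stable order).
#' @export
filter_single_copy_complete <- function(clusters, genome_set) {
  genome_set <- sort(unique(genome_set))
  # membership is judged over the evaluation set only, so enlarging the set
  # can only shrink (or preserve) the result
  keep <- clusters |>
    dplyr::filter(.data$genome_id %in% genome_set) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      ok = dplyr::n() == length(genome_set) && !anyDuplicated(.data$genome_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$ok)
  dplyr::semi_join(clusters, keep, by = "cluster_id")
}

#' Greedy identity clustering for redundancy reduction
#'
#' Longest-first incremental clustering: each sequence joins the first
#' representative to which its global-alignment identity (matches /
#' alignment columns) reaches `threshold`, otherwise it founds a new
#' cluster. Mirrors the classic redundancy-reduction scheme used before
#' single-gene phylogenies.
#'
#' @param seqs Tibble with `id` and `seq` columns, or a named character
#'   vector of sequences.
#' @param threshold Identity threshold in (0, 1]; default 0.90.
#' @return Tibble: `id`, `representative`, `identity` (identity to the
#'   representative; 1 for representatives themselves).
#' @export
greedy_identity_cluster <- function(seqs, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  if (!is.data.frame(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), seq = unname(seqs))
  }
  ord <- order(-nchar(seqs$seq), seqs$id)
  seqs <- seqs[ord, ]
  reps <- integer(0)
  rep_of <- character(nrow(seqs))
  ident <- numeric(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    assigned <- FALSE
    for (r in reps) {
      pid <- global_identity(seqs$seq[i], seqs$seq[r])
      if (pid >= threshold) {
        rep_of[i] <- seqs$id[r]; ident[i] <- pid; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps <- c(reps, i); rep_of[i] <- seqs$id[i]; ident[i] <- 1
    }
  }
  tibble::tibble(id = seqs$id, representative = rep_of, identity = ident) |>
    dplyr::arrange(.data$representative, .data$id)
}

global_identity <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend
  )
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

#' Run the full orthology stage over a set of genomes
#'
#' Convenience wrapper: derive proteomes, all-vs-all hits, RBH for every
#' genome pair, connected-component clusters.
#'
#' @param genomes Named list of `gi_genome`s.
#' @param min_score,min_coverage See [all_vs_all_hits()].
#' @return List with `hits`, `rbh`, `clusters`, and `single_copy` (clusters
#'   passing [filter_single_copy_complete()] over all genomes).
#' @export
orthology_pipeline <- function(genomes, min_score = 50, min_coverage = 0.5) {
  prots <- dplyr::bind_rows(lapply(genomes, proteome))
  hits <- all_vs_all_hits(prots, min_score = min_score, min_coverage = min_coverage)
  ids <- sort(names(genomes))
  rbh <- dplyr::bind_rows(purrr::map(
    utils::combn(ids, 2, simplify = FALSE),
    function(p) reciprocal_best_hits(hits, p[1], p[2])
  ))
  clusters <- cluster_rbh_graph(rbh)
  list(
    hits = hits, rbh = rbh, clusters = clusters,
    single_copy = filter_single_copy_complete(clusters, ids)
  )
}

#' Write ortholog clusters as TSV
#' @param clusters Cluster tibble.
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(clusters, path)
  invisible(path)
}
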