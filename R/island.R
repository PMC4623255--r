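#' Find direct repeats in a contig
#'
#' Exact k-mer seeding (default k = 16) followed by maximal outward
#' extension. With `max_mismatch = 0` reported pairs are maximal exact
#' repeats; with a mismatch budget the seed is extended outward (right,
#' then left) until the budget would be exceeded. Pairs whose copies
#' overlap, whose separation (bases strictly between the copies) falls
#' outside `[min_sep, max_sep]`, or that are contained in a longer
#' reported pair are suppressed.
#'
#' @param contig DNA sequence (single string).
#' @param min_len Minimum repeat length (>= seed size).
#' @param max_mismatch Maximum Hamming mismatches between the copies.
#' @param min_sep,max_sep Allowed separation between the copies in bp.
#' @param k Seed length.
#' @param contig_name Name used in the output.
#' @return Tibble: `contig`, `start1`, `end1`, `start2`, `end2`, `length`,
#'   `mismatches`, `separation`, `orientation` (always `"direct"`).
#' @export
find_direct_repeats <- function(contig, min_len = 40, max_mismatch = 0,
                                min_sep = 5000, max_sep = 200000,
                                k = 16, contig_name = "chr") {
  if (min_len < k) abort("min_len must be >= seed length k")
  L <- nchar(contig)
  empty <- tibble::tibble(
    contig = character(), start1 = integer(), end1 = integer(),
    start2 = integer(), end2 = integer(), length = integer(),
    mismatches = integer(), separation = integer(), orientation = character()
  )
  if (L < min_len) return(empty)
  v <- chars(contig)
  kmers <- substring(contig, 1:(L - k + 1), k:L)
  ord <- order(kmers, method = "radix")
  r <- rle(kmers[ord])
  ends <- cumsum(r$lengths)
  pairs <- list()
  for (gi in which(r$lengths >= 2)) {
    pos <- sort(ord[(ends[gi] - r$lengths[gi] + 1):ends[gi]])
    for (a in seq_len(length(pos) - 1)) {
      for (b in (a + 1):length(pos)) {
        pairs[[length(pairs) + 1]] <- c(pos[a], pos[b])
      }
    }
  }
  if (!length(pairs)) return(empty)
  seeds <- unique(do.call(rbind, pairs))
  # collapse seeds on the same diagonal to one representative
  diag_id <- seeds[, 2] - seeds[, 1]
  reps <- list()
  seen <- character(0)
  for (i in order(diag_id, seeds[, 1])) {
    ext <- extend_repeat(v, seeds[i, 1], seeds[i, 2], k, max_mismatch)
    if (is.null(ext)) next
    key <- paste(ext$s1, ext$s2, ext$len)
    if (key %in% seen) next
    seen <- c(seen, key)
    reps[[length(reps) + 1]] <- ext
  }
  if (!length(reps)) return(empty)
  tab <- dplyr::bind_rows(lapply(reps, function(e) {
    tibble::tibble(
      contig = contig_name,
      start1 = e$s1, end1 = e$s1 + e$len - 1L,
      start2 = e$s2, end2 = e$s2 + e$len - 1L,
      length = e$len, mismatches = e$mm,
      separation = e$s2 - (e$s1 + e$len - 1L) - 1L,
      orientation = "direct"
    )
  }))
  tab <- dplyr::filter(
    tab,
    .data$length >= min_len,
    .data$separation >= min_sep, .data$separation <= max_sep,
    .data$end1 < .data$start2
  )
  if (!nrow(tab)) return(empty)
  tab <- dplyr::distinct(tab)
  # suppress pairs contained in longer pairs
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(nrow(tab))) {
      if (i == j || !keep[i]) next
      if (tab$length[j] > tab$length[i] &&
          tab$start1[i] >= tab$start1[j] && tab$end1[i] <= tab$end1[j] &&
          tab$start2[i] >= tab$start2[j] && tab$end2[i] <= tab$end2[j]) {
        keep[i] <- FALSE
      }
    }
  }
  dplyr::arrange(tab[keep, ], .data$start1, .data$start2)
}

# maximal outward extension of an exact seed; copies are kept non-overlapping
extend_repeat <- function(v, s1, s2, k, max_mismatch) {
  e1 <- s1 + k - 1L; e2 <- s2 + k - 1L
  L <- length(v)
  mm <- 0L
  # extend right
  while (e2 < L && e1 + 1L < s2) {
    nm <- mm + (v[e1 + 1L] != v[e2 + 1L])
    if (nm > max_mismatch) break
    mm <- nm; e1 <- e1 + 1L; e2 <- e2 + 1L
  }
  # extend left
  while (s1 > 1L && s2 - 1L > e1) {
    nm <- mm + (v[s1 - 1L] != v[s2 - 1L])
    if (nm > max_mismatch) break
    mm <- nm; s1 <- s1 - 1L; s2 <- s2 - 1L
  }
  list(s1 = as.integer(s1), s2 = as.integer(s2), len = as.integer(e1 - s1 + 1L), mm = as.integer(mm))
}

#' Locate tRNA-anchored genomic islands from repeat pairs
#'
#' For each direct-repeat pair with at least one copy overlapping a tRNA
#' feature, emits an island call spanning from the end of the proximal
#' repeat copy to the end of the distal copy -- the island carries the
#' distal (duplicated) copy while the intact tRNA stays outside. When two
#' candidate pairs share a tRNA, the longer-spanning pair wins (both are
#' retained in the `"candidates"` attribute); repeat pairs touching no
#' tRNA are reported in the `"unassigned"` attribute, not called.
#'
#' @param genome A `gi_genome`.
#' @param repeats Repeat table from [find_direct_repeats()] (or `NULL` to
#'   compute with defaults).
#' @param ... Passed to [find_direct_repeats()] when `repeats` is `NULL`.
#' @return Tibble of island calls: `genome_id`, `contig`, `start`, `end`,
#'   `length`, `trna_id`, repeat coordinates, `n_genes`, `gene_ids`
#'   (list-column), and evidence flags `ev_repeat`, `ev_trna`.
#' @export
locate_integration_sites <- function(genome, repeats = NULL, ...) {
  if (is.null(repeats)) {
    repeats <- dplyr::bind_rows(lapply(names(genome$contigs), function(cn) {
      find_direct_repeats(genome$contigs[[cn]], contig_name = cn, ...)
    }))
  }
  trnas <- trna_features(genome)
  empty <- tibble::tibble(
    genome_id = character(), contig = character(), start = integer(), end = integer(),
    length = integer(), trna_id = character(),
    rep_start1 = integer(), rep_end1 = integer(),
    rep_start2 = integer(), rep_end2 = integer(), rep_length = integer(),
    n_genes = integer(), gene_ids = list(), ev_repeat = logical(), ev_trna = logical()
  )
  if (!nrow(repeats)) {
    attr(empty, "unassigned") <- repeats
    return(empty)
  }
  hit_trna <- function(cn, s, e) {
    t <- trnas[trnas$contig == cn & trnas$start <= e & trnas$end >= s, ]
    if (nrow(t)) t$feature_id[1] else NA_character_
  }
  repeats$trna_id <- purrr::pmap_chr(
    repeats[, c("contig", "start1", "end1", "start2", "end2")],
    function(contig, start1, end1, start2, end2) {
      hit <- hit_trna(contig, start1, end1)
      if (is.na(hit)) hit <- hit_trna(contig, start2, end2)
      hit
    }
  )
  unassigned <- repeats[is.na(repeats$trna_id), ]
  cand <- repeats[!is.na(repeats$trna_id), ]
  if (!nrow(cand)) {
    attr(empty, "unassigned") <- unassigned
    return(empty)
  }
  cand$span <- cand$end2 - cand$end1
  winners <- cand |>
    dplyr::group_by(.data$contig, .data$trna_id) |>
    dplyr::arrange(dplyr::desc(.data$span), .data$start1, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  cds <- genome$features[genome$features$type == "CDS", ]
  calls <- purrr::pmap(winners, function(contig, end1, end2, trna_id,
                                         start1, start2, length, ...) {
    s <- end1 + 1L; e <- end2
    rep_len <- as.integer(length)
    inside <- cds$feature_id[cds$contig == contig & cds$start >= s & cds$end <= e]
    tibble::tibble(
      genome_id = genome$genome_id, contig = contig,
      start = as.integer(s), end = as.integer(e),
      length = as.integer(e - s + 1L), trna_id = trna_id,
      rep_start1 = as.integer(start1), rep_end1 = as.integer(end1),
      rep_start2 = as.integer(start2), rep_end2 = as.integer(end2),
      rep_length = rep_len,
      n_genes = length(inside), gene_ids = list(inside),
      ev_repeat = TRUE, ev_trna = TRUE
    )
  })
  out <- dplyr::bind_rows(calls)
  attr(out, "unassigned") <- unassigned
  attr(out, "candidates") <- cand
  out
}

#' Delineate islands in a genome
#'
#' Convenience wrapper: [find_direct_repeats()] on every contig, then
#' [locate_integration_sites()].
#'
#' @param genome A `gi_genome`.
#' @inheritParams find_direct_repeats
#' @return Island-call tibble, see [locate_integration_sites()].
#' @export
delineate_islands <- function(genome, min_len = 40, max_mismatch = 0,
                              min_sep = 5000, max_sep = 200000) {
  reps <- dplyr::bind_rows(lapply(names(genome$contigs), function(cn) {
    find_direct_repeats(genome$contigs[[cn]], min_len = min_len,
                        max_mismatch = max_mismatch, min_sep = min_sep,
                        max_sep = max_sep, contig_name = cn)
  }))
  locate_integration_sites(genome, reps)
}

#' Flanking-gene synteny against a non-carrier relative
#'
#' Takes the `m_flank` CDS genes on each side of an island in the carrier,
#' maps them through ortholog clusters into the non-carrier, and asks
#' whether the mapped genes form a contiguous colinear run: the upstream
#' and downstream blocks must be adjacent up to `gap_tolerance` intervening
#' (unmapped) genes. A contiguous flank in the non-carrier is the signature
#' of an empty integration site.
#'
#' @param carrier Carrier `gi_genome`.
#' @param island One island-call row (tibble) for the carrier.
#' @param noncarrier Non-carrier `gi_genome`.
#' @param clusters Ortholog clusters from [cluster_rbh_graph()].
#' @param m_flank Flank size in genes.
#' @param gap_tolerance Allowed intervening genes between the blocks.
#' @return List: `contiguous` (flag), `intervening_gene_count`, `colinear`,
#'   `mapped` (tibble of flank genes and their non-carrier positions).
#' @export
flanking_synteny_score <- function(carrier, island, noncarrier, clusters,
                                   m_flank = 5, gap_tolerance = 1) {
  isl_contig <- island$contig[[1]]; isl_start <- island$start[[1]]; isl_end <- island$end[[1]]
  cds_c <- carrier$features[carrier$features$type == "CDS" &
                              carrier$features$contig == isl_contig, ]
  cds_c <- cds_c[order(cds_c$start), ]
  up <- utils::tail(cds_c$feature_id[cds_c$end < isl_start], m_flank)
  down <- utils::head(cds_c$feature_id[cds_c$start > isl_end], m_flank)
  if (length(up) < m_flank || length(down) < m_flank) {
    warn("fewer than m_flank mappable genes on one side; proceeding with reduced flank")
  }
  cl_c <- clusters[clusters$genome_id == carrier$genome_id, ]
  cl_n <- clusters[clusters$genome_id == noncarrier$genome_id, ]
  cds_n <- noncarrier$features |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::arrange(.data$contig, .data$start) |>
    dplyr::mutate(pos = dplyr::row_number())
  map_one <- function(gid, side) {
    cl <- cl_c$cluster_id[cl_c$gene_id == gid]
    if (!length(cl)) return(NULL)
    tgt <- cl_n$gene_id[cl_n$cluster_id == cl[1]]
    if (length(tgt) != 1) return(NULL)
    pos <- cds_n$pos[cds_n$feature_id == tgt]
    tibble::tibble(side = side, carrier_gene = gid, noncarrier_gene = tgt, pos = pos)
  }
  mapped <- dplyr::bind_rows(
    purrr::map(up, map_one, side = "up"),
    purrr::map(down, map_one, side = "down")
  )
  if (!nrow(mapped) || !any(mapped$side == "up") || !any(mapped$side == "down")) {
    return(list(contiguous = FALSE, intervening_gene_count = NA_integer_,
                colinear = FALSE, mapped = mapped))
  }
  p <- mapped$pos
  colinear <- all(diff(p) > 0) || all(diff(p) < 0)
  upb <- range(mapped$pos[mapped$side == "up"])
  dnb <- range(mapped$pos[mapped$side == "down"])
  if (min(dnb) > max(upb)) {
    intervening <- min(dnb) - max(upb) - 1L
  } else if (min(upb) > max(dnb)) {
    intervening <- min(upb) - max(dnb) - 1L
  } else {
    intervening <- NA_integer_
    colinear <- FALSE
  }
  contiguous <- isTRUE(colinear && !is.na(intervening) && intervening <= gap_tolerance)
  list(contiguous = contiguous,
       intervening_gene_count = as.integer(intervening),
       colinear = colinear, mapped = mapped)
}

#' Expand the island core outward from anchor genes
#'
#' Starting at each anchor locus, walk outward gene-by-gene within the
#' island; a gene joins the core when its ortholog cluster occurs in at
#' least two islands, and a walk stops after `stop_run` consecutive
#' island-specific (unshared) genes. Genes never reached, or reached but
#' unshared, are accessory.
#'
#' @param island_genes Tibble with one row per island gene, ordered by
#'   position within each island: columns `genome_id`, `gene_id`,
#'   `cluster_id`.
#' @param anchors Cluster ids of the anchor genes (e.g. the pcrA-like and
#'   cld-like clusters).
#' @param stop_run Consecutive island-specific genes that terminate a walk.
#' @return List: `core` (cluster ids), `accessory` (named list per
#'   genome), `anchors`.
#' @export
anchor_core_expansion <- function(island_genes, anchors, stop_run = 3) {
  ids <- unique(island_genes$genome_id)
  if (length(ids) < 2) abort("need at least two islands to define a shared core")
  occ <- island_genes |>
    dplyr::distinct(.data$genome_id, .data$cluster_id) |>
    dplyr::count(.data$cluster_id, name = "n_islands")
  shared <- occ$cluster_id[occ$n_islands >= 2]
  if (!any(anchors %in% island_genes$cluster_id)) {
    abort("no anchor cluster present in any island")
  }
  core <- character(0)
  for (gid in ids) {
    cl <- island_genes$cluster_id[island_genes$genome_id == gid]
    for (anc in anchors) {
      a_pos <- which(cl == anc)
      if (!length(a_pos)) next
      for (p0 in a_pos) {
        if (cl[p0] %in% shared) core <- union(core, cl[p0])
        for (dir in c(-1L, 1L)) {
          run <- 0L
          p <- p0 + dir
          while (p >= 1 && p <= length(cl) && run < stop_run) {
            if (cl[p] %in% shared) {
              core <- union(core, cl[p])
              run <- 0L
            } else {
              run <- run + 1L
            }
            p <- p + dir
          }
        }
      }
    }
  }
  accessory <- lapply(stats::setNames(ids, ids), function(gid) {
    setdiff(unique(island_genes$cluster_id[island_genes$genome_id == gid]), core)
  })
  list(core = sort(core), accessory = accessory, anchors = anchors)
}

#' Default mobility marker keyword sets
#'
#' Regular expressions matched (case-insensitively) against CDS product
#' annotations. Configurable because marker vocabularies differ between
#' annotation pipelines.
#'
#' @return Named list of regex strings.
#' @export
default_mobility_markers <- function() {
  list(
    recombinase = "recombinase|integrase|xerD",
    conjugation = "conjugal|conjugation|tra[A-Z]|trb[A-Z]|type IV secretion",
    replication = "plasmid replication|replication initiator|repA",
    insertion_sequence = "transposase|insertion sequence|IS element"
  )
}

#' Classify the mobility mechanism of an island
#'
#' Deterministic, total classification:
#' * `trna_integrative` -- a tRNA-overlapping direct-repeat pair delimits
#'   the island and a site-specific recombinase lies inside it;
#' * `ice` -- conjugation and replication markers inside the island
#'   (integrative and conjugative element);
#' * `composite_transposon` -- the island is flanked on both sides by
#'   insertion-sequence genes whose nucleotide sequences are near-identical
#'   (>= `is_min_identity` over >= `is_min_len` bp);
#' * `unknown` otherwise.
#'
#' When several patterns match, the priority is trna_integrative > ice >
#' composite_transposon, with all evidence reported.
#'
#' @param genome A `gi_genome`.
#' @param island One island-call row (needs `contig`, `start`, `end`, and
#'   the `ev_repeat`/`ev_trna` flags if present).
#' @param markers Marker regex list, see [default_mobility_markers()].
#' @param flank_window bp searched on each side for flanking IS copies.
#' @param is_min_identity,is_min_len Thresholds for "near-identical" IS
#'   copies.
#' @return One-row tibble: `class` plus logical evidence columns.
#' @export
classify_mobility <- function(genome, island, markers = default_mobility_markers(),
                              flank_window = 10000, is_min_identity = 0.95,
                              is_min_len = 500) {
  f <- genome$features
  inside <- f[f$type == "CDS" & f$contig == island$contig &
                f$start >= island$start & f$end <= island$end, ]
  has <- function(rx, tab) any(grepl(rx, tab$product, ignore.case = TRUE))
  ev_recomb <- has(markers$recombinase, inside)
  ev_conj <- has(markers$conjugation, inside)
  ev_rep <- has(markers$replication, inside)
  ev_repeat_trna <- isTRUE(island$ev_repeat) && isTRUE(island$ev_trna)
  left_is <- f[f$type == "CDS" & f$contig == island$contig &
                 f$end < island$start & f$end >= island$start - flank_window &
                 grepl(markers$insertion_sequence, f$product, ignore.case = TRUE), ]
  right_is <- f[f$type == "CDS" & f$contig == island$contig &
                  f$start > island$end & f$start <= island$end + flank_window &
                  grepl(markers$insertion_sequence, f$product, ignore.case = TRUE), ]
  ev_composite <- FALSE
  if (nrow(left_is) && nrow(right_is)) {
    for (i in seq_len(nrow(left_is))) {
      for (j in seq_len(nrow(right_is))) {
        s1 <- substr(genome$contigs[[island$contig]], left_is$start[i], left_is$end[i])
        s2 <- substr(genome$contigs[[island$contig]], right_is$start[j], right_is$end[j])
        if (left_is$strand[i] != right_is$strand[j]) s2 <- revcomp(s2)
        if (nchar(s1) >= is_min_len && nchar(s2) >= is_min_len &&
            nucleotide_identity(s1, s2) >= is_min_identity) {
          ev_composite <- TRUE
        }
      }
    }
  }
  class <- if (ev_repeat_trna && ev_recomb) "trna_integrative"
  else if (ev_conj && ev_rep) "ice"
  else if (ev_composite) "composite_transposon"
  else "unknown"
  tibble::tibble(
    genome_id = genome$genome_id, class = class,
    ev_repeat_trna = ev_repeat_trna, ev_recombinase = ev_recomb,
    ev_conjugation = ev_conj, ev_replication = ev_rep,
    ev_flanking_is = ev_composite
  )
}

nucleotide_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global"
  )
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

#' Write island calls as BED6
#'
#' 0-based half-open intervals; the name field is
#' `<genome_id>|<trna_id>`.
#'
#' @param calls Island-call tibble.
#' @param path Output path.
#' @export
write_islands_bed <- function(calls, path) {
  bed <- tibble::tibble(
    chrom = calls$contig, start = calls$start - 1L, end = calls$end,
    name = paste(calls$genome_id, calls$trna_id, sep = "|"),
    score = 0L, strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
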