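#' Anchor-chained whole-sequence alignment
#'
#' Mauve-style colinear alignment built from maximal unique matches:
#' k-mers (k = `min_anchor`) occurring exactly once in each sequence seed
#' anchors, consecutive-diagonal seeds merge into maximal unique match
#' segments, and the heaviest colinear chain (weight = anchor length,
#' LIS-style dynamic programme) is selected. Gaps between chained anchors
#' are closed by direct base pairing when ref and query gap lengths are
#' equal, by global affine alignment when they differ and both are at most
#' `max_gap`, and are flagged unaligned otherwise (as are one-sided gaps,
#' e.g. an island present only in the reference). Every reference base is
#' assigned to exactly one block.
#'
#' @param ref_seq,query_seq DNA sequences (single strings).
#' @param min_anchor Minimum anchor (and seed) length.
#' @param max_gap Maximum inter-anchor gap closed by alignment.
#' @param contig Contig name recorded in the output.
#' @return A `gi_segment_map`: tibble of blocks with `type`
#'   (`aligned`, `unaligned_ref`, `insertion_query`), reference and query
#'   intervals (1-based inclusive; NA where absent) and gapped alignment
#'   strings for aligned blocks.
#' @export
anchor_chain_align <- function(ref_seq, query_seq, min_anchor = 20,
                               max_gap = 5000, contig = "chr") {
  if (!nzchar(ref_seq) || !nzchar(query_seq)) abort("sequences must be non-empty")
  anchors <- unique_match_anchors(ref_seq, query_seq, min_anchor)
  if (!nrow(anchors)) {
    warn("no unique anchors found; everything unaligned")
    out <- tibble::tibble(
      type = "unaligned_ref", ref_start = 1L, ref_end = nchar(ref_seq),
      query_start = NA_integer_, query_end = NA_integer_,
      ref_aln = NA_character_, query_aln = NA_character_
    )
    return(new_segment_map(out, contig, nchar(ref_seq)))
  }
  chain <- heaviest_colinear_chain(anchors)
  blocks <- chain_to_blocks(chain, ref_seq, query_seq, max_gap)
  new_segment_map(blocks, contig, nchar(ref_seq))
}

new_segment_map <- function(blocks, contig, ref_len) {
  blocks$contig <- contig
  structure(blocks, class = c("gi_segment_map", class(blocks)),
            contig = contig, ref_len = ref_len)
}

# maximal unique match segments as a tibble (r, q, len)
unique_match_anchors <- function(ref_seq, query_seq, k) {
  rkmers <- substring(ref_seq, 1:(nchar(ref_seq) - k + 1), k:nchar(ref_seq))
  qkmers <- substring(query_seq, 1:(nchar(query_seq) - k + 1), k:nchar(query_seq))
  rt <- table_unique(rkmers)
  qt <- table_unique(qkmers)
  common <- intersect(names(rt), names(qt))
  if (!length(common)) return(tibble::tibble(r = integer(), q = integer(), len = integer()))
  r <- rt[common]; q <- qt[common]
  ord <- order(r)
  r <- r[ord]; q <- q[ord]
  # merge runs on the same diagonal
  newrun <- c(TRUE, !(diff(r) == 1 & diff(q) == 1))
  grp <- cumsum(newrun)
  starts <- which(newrun)
  runlen <- tabulate(grp)
  tibble::tibble(
    r = as.integer(r[starts]), q = as.integer(q[starts]),
    len = as.integer(runlen + k - 1L)
  )
}

# positions of strings occurring exactly once, named by string
table_unique <- function(x) {
  ord <- order(x, method = "radix")
  sx <- x[ord]
  r <- rle(sx)
  ends <- cumsum(r$lengths)
  singles <- r$lengths == 1
  stats::setNames(ord[ends[singles]], r$values[singles])
}

# heaviest strictly-colinear non-overlapping chain (weight = anchor length)
heaviest_colinear_chain <- function(anchors) {
  a <- anchors[order(anchors$r, anchors$q), ]
  n <- nrow(a)
  re <- a$r + a$len - 1L
  qe <- a$q + a$len - 1L
  score <- a$len
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    j <- seq_len(i - 1)
    ok <- re[j] < a$r[i] & qe[j] < a$q[i]
    if (any(ok)) {
      cand <- j[ok]
      best <- cand[which.max(score[cand])]
      if (score[best] + a$len[i] > score[i]) {
        score[i] <- score[best] + a$len[i]
        prev[i] <- best
      }
    }
  }
  path <- integer(0)
  i <- which.max(score)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- prev[i]
  }
  a[path, ]
}

chain_to_blocks <- function(chain, ref_seq, query_seq, max_gap) {
  n <- nrow(chain)
  Lr <- nchar(ref_seq); Lq <- nchar(query_seq)
  recs <- vector("list", 2 * n + 4)
  nr <- 0L
  add <- function(type, rs, re, qs, qe) {
    nr <<- nr + 1L
    recs[[nr]] <<- list(type = type, rs = rs, re = re, qs = qs, qe = qe)
  }
  # runs of anchors separated by equal-length small gaps coalesce into one
  # directly paired block (substitution-only stretch); other gaps break runs
  cur_rs <- chain$r[1]; cur_qs <- chain$q[1]
  lead_r <- chain$r[1] - 1L; lead_q <- chain$q[1] - 1L
  if (lead_r > 0 && lead_r == lead_q && lead_r <= max_gap) {
    cur_rs <- 1L; cur_qs <- 1L
  } else {
    if (lead_r > 0) add("unaligned_ref", 1L, lead_r, NA, NA)
    if (lead_q > 0) add("insertion_query", NA, NA, 1L, lead_q)
  }
  for (i in seq_len(n)) {
    re <- chain$r[i] + chain$len[i] - 1L
    qe <- chain$q[i] + chain$len[i] - 1L
    if (i < n) {
      rg <- chain$r[i + 1] - re - 1L
      qg <- chain$q[i + 1] - qe - 1L
      if (rg == qg && rg <= max_gap) next  # extend the direct-paired run
      add("aligned", cur_rs, re, cur_qs, qe)
      if (rg > 0 && qg > 0 && rg <= max_gap && qg <= max_gap) {
        add("gap_align", re + 1L, chain$r[i + 1] - 1L, qe + 1L, chain$q[i + 1] - 1L)
      } else {
        if (rg > 0) add("unaligned_ref", re + 1L, chain$r[i + 1] - 1L, NA, NA)
        if (qg > 0) add("insertion_query", NA, NA, qe + 1L, chain$q[i + 1] - 1L)
      }
      cur_rs <- chain$r[i + 1]; cur_qs <- chain$q[i + 1]
    } else {
      tr <- Lr - re; tq <- Lq - qe
      if (tr > 0 && tr == tq && tr <= max_gap) {
        add("aligned", cur_rs, Lr, cur_qs, Lq)
      } else {
        add("aligned", cur_rs, re, cur_qs, qe)
        if (tr > 0) add("unaligned_ref", re + 1L, Lr, NA, NA)
        if (tq > 0) add("insertion_query", NA, NA, qe + 1L, Lq)
      }
    }
  }
  recs <- recs[seq_len(nr)]
  blocks <- tibble::tibble(
    type = vapply(recs, `[[`, character(1), "type"),
    ref_start = as.integer(vapply(recs, function(x) as.integer(x$rs %||% NA_integer_), integer(1))),
    ref_end = as.integer(vapply(recs, function(x) as.integer(x$re %||% NA_integer_), integer(1))),
    query_start = as.integer(vapply(recs, function(x) as.integer(x$qs %||% NA_integer_), integer(1))),
    query_end = as.integer(vapply(recs, function(x) as.integer(x$qe %||% NA_integer_), integer(1))),
    ref_aln = NA_character_, query_aln = NA_character_
  )
  direct <- blocks$type == "aligned"
  blocks$ref_aln[direct] <- substring(ref_seq, blocks$ref_start[direct], blocks$ref_end[direct])
  blocks$query_aln[direct] <- substring(query_seq, blocks$query_start[direct], blocks$query_end[direct])
  for (i in which(blocks$type == "gap_align")) {
    rsub <- substr(ref_seq, blocks$ref_start[i], blocks$ref_end[i])
    qsub <- substr(query_seq, blocks$query_start[i], blocks$query_end[i])
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(rsub), Biostrings::DNAString(qsub), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2
    )
    blocks$ref_aln[i] <- as.character(Biostrings::alignedPattern(pa))
    blocks$query_aln[i] <- as.character(Biostrings::alignedSubject(pa))
  }
  blocks$type[blocks$type == "gap_align"] <- "aligned"
  blocks
}

#' Call SNPs from a segment map
#'
#' One record per mismatched aligned column with unambiguous bases on both
#' sides; gap and non-ACGT columns are skipped. Records are sorted by
#' reference position.
#'
#' @param map A `gi_segment_map`.
#' @return Tibble: `contig`, `pos` (1-based reference), `ref`, `alt`.
#' @export
call_snps <- function(map) {
  aligned <- map[map$type == "aligned", ]
  rows <- vector("list", nrow(aligned))
  acgt <- charToRaw("ACGT")
  for (i in seq_len(nrow(aligned))) {
    ra <- charToRaw(aligned$ref_aln[i])
    qa <- charToRaw(aligned$query_aln[i])
    refpos <- cumsum(ra != charToRaw("-")) + aligned$ref_start[i] - 1L
    mism <- which(ra != qa & ra %in% acgt & qa %in% acgt)
    if (length(mism)) {
      rows[[i]] <- tibble::tibble(
        contig = aligned$contig[i],
        pos = as.integer(refpos[mism]),
        ref = strsplit(rawToChar(ra[mism]), "")[[1]],
        alt = strsplit(rawToChar(qa[mism]), "")[[1]]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character())
  }
  dplyr::arrange(out, .data$pos)
}

#' Label SNPs by genomic region
#'
#' Assigns each SNP exactly one label: `unaligned_adjacent` when within
#' `adj_window` bp of an unaligned reference block (assembly-edge caution),
#' else `island` when inside the island interval, else `backbone`.
#'
#' @param snps SNP tibble from [call_snps()].
#' @param map The `gi_segment_map` the SNPs came from.
#' @param island Optional island interval (list or one-row tibble with
#'   `start`, `end`).
#' @param adj_window Adjacency window in bp.
#' @return The SNP tibble with a `region` column.
#' @export
label_snp_regions <- function(snps, map, island = NULL, adj_window = 100) {
  region <- rep("backbone", nrow(snps))
  if (!is.null(island) && nrow(snps)) {
    region[snps$pos >= island$start[[1]] & snps$pos <= island$end[[1]]] <- "island"
  }
  un <- map[map$type == "unaligned_ref", ]
  if (nrow(un) && nrow(snps)) {
    for (i in seq_len(nrow(un))) {
      near <- snps$pos >= un$ref_start[i] - adj_window & snps$pos <= un$ref_end[i] + adj_window
      region[near] <- "unaligned_adjacent"
    }
  }
  snps$region <- region
  snps
}

#' Windowed SNP histogram
#'
#' Tiles `region` with fixed windows starting at its left end; the last
#' partial window is retained with its true effective length. Window counts
#' partition the SNPs inside the region.
#'
#' @param snps SNP tibble (needs `pos`).
#' @param region Interval with `start`, `end` (1-based inclusive).
#' @param window Window size in bp (default 500, the classic island-plot
#'   resolution).
#' @return A `gi_window_track` tibble: `start`, `end`, `effective_length`,
#'   `n_snps`.
#' @export
window_snp_histogram <- function(snps, region, window = 500) {
  if (window < 1) abort("window must be >= 1")
  s <- region$start[[1]]; e <- region$end[[1]]
  starts <- seq.int(s, e, by = window)
  ends <- pmin(starts + window - 1L, e)
  n <- if (nrow(snps)) {
    inreg <- snps$pos[snps$pos >= s & snps$pos <= e]
    if (length(inreg)) tabulate(findInterval(inreg, starts), nbins = length(starts)) else rep(0L, length(starts))
  } else rep(0L, length(starts))
  structure(
    tibble::tibble(
      start = as.integer(starts), end = as.integer(ends),
      effective_length = as.integer(ends - starts + 1L), n_snps = as.integer(n)
    ),
    class = c("gi_window_track", class(tibble::tibble())),
    region = c(s, e), window = window
  )
}

#' SNP frequency of a region
#'
#' Frequency is SNPs per aligned reference bp by default (draft assemblies
#' leave unaligned gaps), with the total-length denominator also reported.
#'
#' @param snps SNP tibble.
#' @param region Interval with `start`, `end`.
#' @param map A `gi_segment_map` (for the aligned-bp denominator).
#' @param denominator `"aligned"` or `"total"` -- which frequency to expose
#'   as `frequency`.
#' @return One-row tibble: `n_snps`, `aligned_bp`, `total_bp`,
#'   `freq_aligned`, `freq_total`, `frequency`.
#' @export
region_snp_frequency <- function(snps, region, map, denominator = c("aligned", "total")) {
  denominator <- match.arg(denominator)
  s <- region$start[[1]]; e <- region$end[[1]]
  total <- e - s + 1
  aligned <- map[map$type == "aligned", ]
  aligned_bp <- if (nrow(aligned)) {
    sum(pmax(0, pmin(aligned$ref_end, e) - pmax(aligned$ref_start, s) + 1))
  } else 0
  k <- if (nrow(snps)) sum(snps$pos >= s & snps$pos <= e) else 0L
  if ((denominator == "aligned" && aligned_bp == 0) || total == 0) {
    abort("zero-length denominator: frequency undefined")
  }
  tibble::tibble(
    n_snps = as.integer(k), aligned_bp = as.integer(aligned_bp),
    total_bp = as.integer(total),
    freq_aligned = if (aligned_bp > 0) k / aligned_bp else NA_real_,
    freq_total = k / total,
    frequency = if (denominator == "aligned") k / aligned_bp else k / total
  )
}

#' Island-versus-backbone SNP divergence contrast
#'
#' One-sided exact binomial depletion test: under the backbone rate
#' `k2/n2`, the probability of observing at most `k1` SNPs over the
#' island's `n1` aligned bp is `P(X <= k1), X ~ Binomial(n1, k2/n2)`.
#' Classification: `recent_independent` when `p < alpha` and the
#' island/backbone frequency ratio is below `ratio_cut` (the island is too
#' conserved to share the backbone's divergence history);
#' `ancestral_vertical` when the ratio lies in `vertical_band`;
#' `indeterminate` otherwise.
#'
#' @param island_k,island_n Island SNP count and aligned bp.
#' @param backbone_k,backbone_n Backbone SNP count and aligned bp.
#' @param alpha Significance level.
#' @param ratio_cut Maximum frequency ratio for a recent call.
#' @param vertical_band Ratio interval consistent with vertical descent.
#' @param alternative `"less"` (depletion, default) or `"two.sided"`.
#' @return A `gi_contrast` object (list with `island`, `backbone`,
#'   `ratio`, `p_value`, `call` and the thresholds used).
#' @export
acquisition_contrast_test <- function(island_k, island_n, backbone_k, backbone_n,
                                      alpha = 0.01, ratio_cut = 0.1,
                                      vertical_band = c(0.5, 2),
                                      alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (island_n <= 0 || backbone_n <= 0) abort("region lengths must be positive")
  if (backbone_k == 0) abort("backbone SNP count is zero: contrast undefined")
  rate <- backbone_k / backbone_n
  p_less <- stats::pbinom(island_k, island_n, rate)
  p <- if (alternative == "less") p_less else min(1, 2 * min(p_less, 1 - stats::pbinom(island_k - 1, island_n, rate)))
  f1 <- island_k / island_n
  f2 <- backbone_k / backbone_n
  ratio <- f1 / f2
  call <- if (p < alpha && ratio < ratio_cut) "recent_independent"
  else if (ratio >= vertical_band[1] && ratio <= vertical_band[2]) "ancestral_vertical"
  else "indeterminate"
  structure(
    list(
      island = list(k = island_k, n = island_n, frequency = f1),
      backbone = list(k = backbone_k, n = backbone_n, frequency = f2),
      ratio = ratio, p_value = p, call = call,
      alpha = alpha, ratio_cut = ratio_cut, vertical_band = vertical_band,
      alternative = alternative
    ),
    class = "gi_contrast"
  )
}

#' @export
print.gi_contrast <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<gi_contrast> island %d/%d (%.4g%%) vs backbone %d/%d (%.4g%%)\n",
      "  ratio %.4g, one-sided exact binomial p = %.3g -> %s\n"
    ),
    x$island$k, x$island$n, 100 * x$island$frequency,
    x$backbone$k, x$backbone$n, 100 * x$backbone$frequency,
    x$ratio, x$p_value, x$call
  ))
  invisible(x)
}

#' Annotate the coding effect of SNPs
#'
#' Strand-aware codon translation of reference versus alternate allele for
#' every SNP that falls inside a CDS of the reference genome. Classes:
#' `synonymous`, `nonsynonymous` (with substitution string `"X<pos>Y"`,
#' 1-based residue), `nonsense` (internal stop gained), `start_loss`
#' (initiator codon no longer a start). SNPs in CDSs whose length is not a
#' multiple of 3 are reported `unclassified`.
#'
#' @param snps SNP tibble from [call_snps()].
#' @param genome Reference `gi_genome`.
#' @return Tibble: SNP columns plus `gene_id`, `classification`,
#'   `substitution` (present iff nonsynonymous).
#' @export
annotate_coding_effect <- function(snps, genome) {
  cds <- genome$features[genome$features$type == "CDS", ]
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    hit <- cds[cds$contig == snps$contig[i] & cds$start <= snps$pos[i] & cds$end >= snps$pos[i], ]
    if (!nrow(hit)) next
    hit <- hit[1, ]
    len <- hit$end - hit$start + 1
    if (len %% 3 != 0) {
      out[[i]] <- dplyr::bind_cols(snps[i, ], tibble::tibble(
        gene_id = hit$feature_id, classification = "unclassified",
        substitution = NA_character_
      ))
      next
    }
    cds_seq <- feature_seq(genome, hit$feature_id)
    if (hit$strand == "+") {
      cpos <- snps$pos[i] - hit$start + 1L
      alt <- snps$alt[i]
    } else {
      cpos <- hit$end - snps$pos[i] + 1L
      alt <- chartr("ACGT", "TGCA", snps$alt[i])
    }
    ci <- (cpos - 1L) %/% 3L + 1L
    off <- (cpos - 1L) %% 3L + 1L
    ref_codon <- substr(cds_seq, 3 * ci - 2, 3 * ci)
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt
    aa_ref <- unname(Biostrings::GENETIC_CODE[ref_codon])
    aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
    classification <-
      if (ci == 1 && !(alt_codon %in% START_CODONS)) "start_loss"
      else if (aa_alt == "*" && ci < len / 3) "nonsense"
      else if (identical(aa_ref, aa_alt)) "synonymous"
      else "nonsynonymous"
    substitution <- if (classification == "nonsynonymous") {
      paste0(aa_ref, ci, aa_alt)
    } else NA_character_
    out[[i]] <- dplyr::bind_cols(snps[i, ], tibble::tibble(
      gene_id = hit$feature_id, classification = classification,
      substitution = substitution
    ))
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- dplyr::bind_cols(
      snps[0, ],
      tibble::tibble(gene_id = character(), classification = character(),
                     substitution = character())
    )
  }
  res
}

#' Reference-vs-query SNP scan
#'
#' Full divergence stage for one query against a reference: anchor-chain
#' alignment, SNP calling, region labelling, windowed histogram over the
#' island (when given) and the island-vs-backbone contrast. Backbone
#' excludes the island interval.
#'
#' @param ref,query `gi_genome`s (first contig is scanned).
#' @param island Optional island interval (`start`, `end`) on the
#'   reference.
#' @param window Window size for the histogram.
#' @param min_anchor,max_gap See [anchor_chain_align()].
#' @param min_island_aligned Minimum fraction of the island interval that
#'   must be alignment-covered for island frequencies and the contrast to
#'   be defined; queries that do not carry the island report an undefined
#'   (n/a) contrast instead.
#' @param ... Passed to [acquisition_contrast_test()].
#' @return List with `map`, `snps` (region-labelled), `windows` (island
#'   track or NULL), `island_freq`, `backbone_freq`, `contrast` (NULL when
#'   no island given).
#' @export
snp_scan <- function(ref, query, island = NULL, window = 500,
                     min_anchor = 20, max_gap = 5000,
                     min_island_aligned = 0.05, ...) {
  cn <- names(ref$contigs)[1]
  map <- anchor_chain_align(ref$contigs[[cn]], query$contigs[[names(query$contigs)[1]]],
                            min_anchor = min_anchor, max_gap = max_gap, contig = cn)
  snps <- label_snp_regions(call_snps(map), map, island)
  if (is.null(island)) {
    return(list(map = map, snps = snps, windows = NULL,
                island_freq = NULL, backbone_freq = NULL, contrast = NULL))
  }
  ref_len <- attr(map, "ref_len")
  aligned <- map[map$type == "aligned", ]
  isl_aligned <- if (nrow(aligned)) {
    sum(pmax(0, pmin(aligned$ref_end, island$end[[1]]) -
               pmax(aligned$ref_start, island$start[[1]]) + 1))
  } else 0
  isl_len <- island$end[[1]] - island$start[[1]] + 1
  if (isl_aligned < min_island_aligned * isl_len) {
    # query does not carry the island (or it fell in an assembly gap):
    # frequencies and the contrast are undefined for this pair
    return(list(
      map = map, snps = snps,
      windows = window_snp_histogram(snps[snps$region == "island", ], island, window),
      island_freq = NULL, backbone_freq = NULL, contrast = NULL
    ))
  }
  isl_freq <- region_snp_frequency(
    snps[snps$region == "island", ], island, map
  )
  backbone_snps <- snps[snps$region == "backbone", ]
  bb_regions <- list(
    list(start = 1, end = island$start[[1]] - 1),
    list(start = island$end[[1]] + 1, end = ref_len)
  )
  bb <- lapply(Filter(function(r) r$end >= r$start, bb_regions), function(r) {
    region_snp_frequency(backbone_snps, r, map)
  })
  bb_k <- sum(vapply(bb, function(x) x$n_snps, integer(1)))
  bb_n <- sum(vapply(bb, function(x) x$aligned_bp, integer(1)))
  contrast <- acquisition_contrast_test(
    isl_freq$n_snps, isl_freq$aligned_bp, bb_k, bb_n, ...
  )
  list(
    map = map, snps = snps,
    windows = window_snp_histogram(snps[snps$region == "island", ], island, window),
    island_freq = isl_freq,
    backbone_freq = tibble::tibble(
      n_snps = bb_k, aligned_bp = bb_n,
      frequency = bb_k / bb_n
    ),
    contrast = contrast
  )
}

#' Write SNPs as a minimal VCF
#'
#' CHROM/POS (1-based)/REF/ALT with the region label in INFO.
#'
#' @param snps Labelled SNP tibble.
#' @param path Output path.
#' @param sample_name Query name recorded in the header.
#' @export
write_snp_vcf <- function(snps, path, sample_name = "query") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=islescan; query=%s", sample_name),
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"island/backbone label\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  region <- if ("region" %in% names(snps)) snps$region else rep(".", nrow(snps))
  body <- if (nrow(snps)) {
    paste(snps$contig, snps$pos, ".", snps$ref, snps$alt, ".", "PASS",
          paste0("REGION=", region), sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a window track as bedGraph
#' @param track A `gi_window_track`.
#' @param path Output path.
#' @param chrom Contig name.
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  lines <- c(
    "track type=bedGraph name=snp_windows",
    if (nrow(track)) paste(chrom, track$start - 1L, track$end, track$n_snps, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
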