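#' Protein multiple alignments
#'
#' Alignments are named character vectors of equal-length gapped rows
#' (gap character `-`), with class `gi_alignment`. [progressive_align()]
#' produces them; [conserved_block_filter()] trims them.
#'
#' @param rows Named character vector of gapped sequences.
#' @return A `gi_alignment`.
#' @export
new_alignment <- function(rows) {
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    abort("alignment rows must have unique names")
  }
  if (length(unique(nchar(rows))) > 1) abort("alignment rows must have equal length")
  structure(rows, class = "gi_alignment")
}

#' @export
print.gi_alignment <- function(x, ...) {
  cat(sprintf("<gi_alignment> %d taxa x %d columns\n", length(x), if (length(x)) nchar(x[[1]]) else 0))
  invisible(x)
}

#' Alignment as a character matrix (taxa x columns)
#' @param aln A `gi_alignment`.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Remove gaps from one alignment row
#' @param aln A `gi_alignment`.
#' @param taxon Row name.
#' @export
ungap_row <- function(aln, taxon) gsub("-", "", aln[[taxon]], fixed = TRUE)

# substitution matrix by name, as a plain matrix
get_submat <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  as.matrix(get(name, envir = e))
}

aa_alphabet <- function(submat) rownames(submat)

# residue-count profile (alphabet x columns); gaps contribute nothing
profile_counts <- function(rows_mat, alphabet) {
  K <- length(alphabet)
  L <- ncol(rows_mat)
  out <- matrix(0, K, L)
  for (k in seq_len(K)) out[k, ] <- colSums(rows_mat == alphabet[k])
  out
}

#' Progressive multiple alignment
#'
#' MUSCLE-style progressive scheme: a 3-mer count distance between all
#' sequence pairs feeds a UPGMA guide tree, and profiles are merged along
#' the tree with a profile-profile Needleman-Wunsch (affine gaps, average
#' column-pair substitution score). Gaps are only ever inserted -- residues
#' are never altered -- so ungapping any row reproduces its input sequence.
#'
#' @param seqs Named character vector of protein sequences (or tibble with
#'   `id` and `seq` columns).
#' @param matrix Substitution matrix name.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A `gi_alignment` containing every input row, in input order.
#' @export
progressive_align <- function(seqs, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$id)
  if (!length(seqs)) abort("no sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (any(!nzchar(seqs))) abort("sequences must be non-empty")
  if (length(seqs) == 1) return(new_alignment(seqs))
  submat <- get_submat(matrix)
  alphabet <- aa_alphabet(submat)
  mats <- lapply(seqs, function(s) matrix(chars(s), nrow = 1, dimnames = list(NULL, NULL)))
  for (i in seq_along(mats)) rownames(mats[[i]]) <- names(seqs)[i]
  profs <- lapply(mats, profile_counts, alphabet = alphabet)
  if (length(seqs) == 2) {
    merged <- merge_profiles(mats[[1]], mats[[2]], profs[[1]], profs[[2]],
                             submat, gap_open, gap_extend)
    return(alignment_from_matrix(merged$rows, names(seqs)))
  }
  d <- kmer_distance(seqs, k = 3)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  node_rows <- mats
  node_profs <- profs
  merged_rows <- vector("list", nrow(hc$merge))
  merged_profs <- vector("list", nrow(hc$merge))
  fetch <- function(v) {
    if (v < 0) list(rows = node_rows[[-v]], prof = node_profs[[-v]])
    else list(rows = merged_rows[[v]], prof = merged_profs[[v]])
  }
  for (s in seq_len(nrow(hc$merge))) {
    a <- fetch(hc$merge[s, 1]); b <- fetch(hc$merge[s, 2])
    res <- merge_profiles(a$rows, b$rows, a$prof, b$prof, submat, gap_open, gap_extend)
    merged_rows[[s]] <- res$rows
    merged_profs[[s]] <- res$prof
  }
  final <- merged_rows[[nrow(hc$merge)]]
  alignment_from_matrix(final, names(seqs))
}

alignment_from_matrix <- function(rows_mat, order_names) {
  rows <- apply(rows_mat, 1, paste, collapse = "")
  new_alignment(rows[order_names])
}

merge_profiles <- function(rowsA, rowsB, profA, profB, submat, gap_open, gap_extend) {
  ops <- .profile_nw_align(profA, profB, submat, gap_open, gap_extend)
  L <- length(ops)
  useA <- ops %in% c(1L, 3L)
  useB <- ops %in% c(1L, 2L)
  newA <- matrix("-", nrow(rowsA), L, dimnames = list(rownames(rowsA), NULL))
  newB <- matrix("-", nrow(rowsB), L, dimnames = list(rownames(rowsB), NULL))
  newA[, useA] <- rowsA
  newB[, useB] <- rowsB
  rows <- rbind(newA, newB)
  list(rows = rows, prof = profile_counts(rows, aa_alphabet(submat)))
}

# pairwise 3-mer count distance: 1 - shared/min possible
kmer_distance <- function(seqs, k = 3) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      common <- intersect(names(ci), names(cj))
      shared <- sum(pmin(ci[common], cj[common]))
      denom <- max(1, min(sum(ci), sum(cj)))
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

#' Pairwise global profile alignment score
#'
#' Exposed mainly so the two-sequence case of [progressive_align()] can be
#' compared against a plain pairwise Needleman-Wunsch.
#'
#' @param a,b Protein sequences.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return Numeric score.
#' @export
pairwise_global_score <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  submat <- get_submat(matrix)
  alphabet <- aa_alphabet(submat)
  pa <- profile_counts(matrix(chars(a), nrow = 1), alphabet)
  pb <- profile_counts(matrix(chars(b), nrow = 1), alphabet)
  .profile_nw_score(pa, pb, submat, gap_open, gap_extend)
}

#' Conserved-block trimming of an alignment
#'
#' Relaxed Gblocks-style column filter. Rules, applied in order:
#'
#' 1. Columns with gap fraction > `max_gap_frac` are always removed.
#' 2. A column is *conserved* if its most frequent residue occurs in at
#'    least `min_conserved_frac` of the rows, and *highly conserved* at
#'    `min_flank_frac`.
#' 3. Runs of more than `max_nonconserved_run` consecutive non-conserved
#'    (but gap-acceptable) columns are removed.
#' 4. The surviving columns form blocks (contiguity judged on surviving
#'    positions); each block is trimmed so it starts and ends on a highly
#'    conserved column, and blocks shorter than `min_block_len` are
#'    dropped.
#'
#' Defaults follow the relaxed parameterisation that aims to keep all
#' informative sites.
#'
#' @param aln A `gi_alignment`.
#' @param min_conserved_frac,min_flank_frac,max_nonconserved_run,min_block_len,max_gap_frac
#'   Filter parameters, see rules above.
#' @return List with `alignment` (trimmed `gi_alignment`) and
#'   `kept_columns` (integer indices into the input columns).
#' @export
conserved_block_filter <- function(aln, min_conserved_frac = 0.5 + 1e-9,
                                   min_flank_frac = 0.85,
                                   max_nonconserved_run = 8,
                                   min_block_len = 5, max_gap_frac = 0.5) {
  stopifnot(min_conserved_frac >= 0, min_conserved_frac <= 1,
            min_flank_frac >= 0, min_flank_frac <= 1,
            max_gap_frac >= 0, max_gap_frac <= 1)
  m <- alignment_matrix(aln)
  st <- column_status(m, min_conserved_frac, min_flank_frac, max_gap_frac)
  keep <- st$good
  # rule 3: long non-conserved runs (within gap-acceptable columns)
  r <- rle(ifelse(!st$good, "bad", ifelse(st$conserved, "cons", "non")))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] == "non" && r$lengths[i] > max_nonconserved_run) {
      keep[starts[i]:ends[i]] <- FALSE
    }
  }
  # rule 4: blocks, flank trimming, minimum length
  kept <- integer(0)
  kr <- rle(keep)
  kends <- cumsum(kr$lengths)
  kstarts <- kends - kr$lengths + 1
  for (i in seq_along(kr$values)) {
    if (!kr$values[i]) next
    block <- kstarts[i]:kends[i]
    hc <- which(st$highly[block])
    if (!length(hc)) next
    block <- block[min(hc):max(hc)]
    if (length(block) < min_block_len) next
    kept <- c(kept, block)
  }
  trimmed <- if (length(kept)) {
    apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  } else {
    stats::setNames(rep("", nrow(m)), rownames(m))
  }
  list(alignment = new_alignment(trimmed), kept_columns = kept)
}

column_status <- function(m, min_conserved_frac, min_flank_frac, max_gap_frac) {
  n <- nrow(m)
  gap_frac <- colMeans(m == "-")
  top <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    max(tabulate(factor(col)))
  }) / n
  good <- gap_frac <= max_gap_frac
  list(
    good = good,
    conserved = good & top >= min_conserved_frac,
    highly = good & top >= min_flank_frac
  )
}
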