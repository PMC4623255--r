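#' Concatenate per-locus alignments into a supermatrix
#'
#' Every locus must contain exactly one row per taxon (guaranteed upstream
#' by the single-copy-complete filter). Loci are concatenated in list order
#' and the partition map records each locus' column interval (1-based
#' inclusive).
#'
#' @param alignments Named list of `gi_alignment`s keyed by locus id.
#' @param taxa Taxon order; defaults to the (sorted) taxa of the first
#'   locus.
#' @return A `gi_supermatrix`: list with `alignment` (`gi_alignment`) and
#'   `partitions` (tibble: `locus_id`, `start`, `end`).
#' @export
concatenate_supermatrix <- function(alignments, taxa = NULL) {
  if (!length(alignments)) abort("no alignments")
  if (is.null(names(alignments))) names(alignments) <- paste0("locus_", seq_along(alignments))
  if (is.null(taxa)) taxa <- sort(names(alignments[[1]]))
  for (id in names(alignments)) {
    missing <- setdiff(taxa, names(alignments[[id]]))
    if (length(missing)) {
      abort(sprintf("locus %s lacks taxa: %s", id, paste(missing, collapse = ", ")))
    }
  }
  lens <- vapply(alignments, function(a) nchar(a[[1]]), numeric(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  rows <- vapply(taxa, function(tx) {
    paste(vapply(alignments, function(a) a[[tx]], character(1)), collapse = "")
  }, character(1))
  structure(
    list(
      alignment = new_alignment(rows),
      partitions = tibble::tibble(
        locus_id = names(alignments),
        start = as.integer(starts), end = as.integer(ends)
      )
    ),
    class = "gi_supermatrix"
  )
}

#' @export
print.gi_supermatrix <- function(x, ...) {
  cat(sprintf(
    "<gi_supermatrix> %d taxa x %d columns, %d loci\n",
    length(x$alignment), nchar(x$alignment[[1]]), nrow(x$partitions)
  ))
  invisible(x)
}

#' Extract one locus back out of a supermatrix
#' @param sm A `gi_supermatrix`.
#' @param locus_id Locus name from the partition map.
#' @return A `gi_alignment`.
#' @export
slice_locus <- function(sm, locus_id) {
  p <- sm$partitions[sm$partitions$locus_id == locus_id, ]
  if (nrow(p) != 1) abort(paste("unknown locus:", locus_id))
  new_alignment(vapply(unclass(sm$alignment), substr, character(1), p$start, p$end))
}

#' Poisson-corrected protein distance matrix
#'
#' For each taxon pair, `p` is the mismatch fraction over columns where
#' both rows are ungapped, and the distance is `d = -ln(1 - p)`. Pairs
#' with `p >= 1 - 1/20` (beyond the 20-letter saturation point) are capped
#' at that bound and flagged in the `"saturated"` attribute; a pair with no
#' shared ungapped columns is an error.
#'
#' @param sm A `gi_supermatrix` or `gi_alignment`.
#' @return Symmetric numeric matrix with zero diagonal and a `"saturated"`
#'   attribute (tibble of flagged pairs, possibly empty).
#' @export
poisson_distance_matrix <- function(sm) {
  aln <- if (inherits(sm, "gi_supermatrix")) sm$alignment else sm
  taxa <- names(aln)
  n <- length(taxa)
  bytes <- lapply(unclass(aln), charToRaw)
  gap <- charToRaw("-")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- list()
  p_max <- 1 - 1 / 20
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- bytes[[i]] != gap & bytes[[j]] != gap
      ns <- sum(shared)
      if (ns == 0) abort(sprintf("no shared ungapped columns between %s and %s", taxa[i], taxa[j]))
      p <- sum(bytes[[i]][shared] != bytes[[j]][shared]) / ns
      if (p >= p_max) {
        sat[[length(sat) + 1]] <- tibble::tibble(taxon_a = taxa[i], taxon_b = taxa[j], p = p)
        p <- p_max - 1e-9
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  attr(d, "saturated") <- if (length(sat)) dplyr::bind_rows(sat) else
    tibble::tibble(taxon_a = character(), taxon_b = character(), p = numeric())
  d
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' Space-delimited relaxed PHYLIP (taxon names up to 250 characters),
#' suitable as input to external maximum-likelihood programs.
#'
#' @param sm A `gi_supermatrix`.
#' @param path Output path.
#' @export
write_phylip <- function(sm, path) {
  aln <- sm$alignment
  lines <- c(
    sprintf(" %d %d", length(aln), nchar(aln[[1]])),
    paste(substr(names(aln), 1, 250), unclass(aln))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' One line per locus: `PROT, <locus> = <start>-<end>` with 1-based
#' inclusive column intervals.
#'
#' @param sm A `gi_supermatrix`.
#' @param path Output path.
#' @export
write_partitions <- function(sm, path) {
  p <- sm$partitions
  writeLines(sprintf("PROT, %s = %d-%d", p$locus_id, p$start, p$end), path)
  invisible(path)
}
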