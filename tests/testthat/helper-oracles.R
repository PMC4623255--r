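# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain dynamic programmes, exhaustive
# enumeration, and log-space summation.

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  as.matrix(get("BLOSUM62", envir = e))
}

# Gotoh local alignment score by explicit DP (gap of length g costs
# open + g * ext)
sw_local_score_oracle <- function(a, b, submat = blosum62(), open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Gotoh global score by explicit DP (same gap convention)
nw_global_score_oracle <- function(a, b, submat = blosum62(), open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext, Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext, X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# connected components by hand-rolled union-find over (genome, gene) keys
union_find_components <- function(edges_a, edges_b) {
  parent <- list()
  find <- function(x) {
    while (!identical(parent[[x]], x)) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in unique(c(edges_a, edges_b))) parent[[k]] <- k
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (!identical(ra, rb)) parent[[ra]] <- rb
  }
  vapply(names(parent), find, character(1))
}

# lower binomial tail by log-space summation (no pbinom)
binom_tail_oracle <- function(k, n, p) {
  i <- 0:k
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# exact direct repeats by diagonal run scanning (quadratic, exact matches)
brute_force_repeats <- function(contig, min_len, min_sep, max_sep) {
  v <- strsplit(contig, "")[[1]]
  L <- length(v)
  res <- list()
  for (d in seq_len(L - 1)) {
    len_cmp <- L - d
    eq <- v[1:len_cmp] == v[(1 + d):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values & r$lengths >= min_len)) {
      s1 <- starts[i]; len <- r$lengths[i]
      # truncate so the copies do not overlap
      len <- min(len, d)
      if (len < min_len) next
      e1 <- s1 + len - 1
      s2 <- s1 + d; e2 <- e1 + d
      sep <- s2 - e1 - 1
      if (sep >= min_sep && sep <= max_sep) {
        res[[length(res) + 1]] <- c(s1, e1, s2, e2, len)
      }
    }
  }
  if (!length(res)) {
    return(tibble::tibble(start1 = integer(), end1 = integer(),
                          start2 = integer(), end2 = integer(), length = integer()))
  }
  tab <- as.data.frame(do.call(rbind, res))
  names(tab) <- c("start1", "end1", "start2", "end2", "length")
  tab <- unique(tab)
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(nrow(tab))) {
      if (i == j) next
      if (tab$length[j] > tab$length[i] &&
          tab$start1[i] >= tab$start1[j] && tab$end1[i] <= tab$end1[j] &&
          tab$start2[i] >= tab$start2[j] && tab$end2[i] <= tab$end2[j]) keep[i] <- FALSE
    }
  }
  tab <- tab[keep, ]
  tibble::as_tibble(tab[order(tab$start1, tab$start2), ])
}

# heaviest colinear chain by exhaustive subset enumeration (<= 15 anchors)
brute_force_chain_weight <- function(anchors) {
  n <- nrow(anchors)
  best <- 0
  re <- anchors$r + anchors$len - 1
  qe <- anchors$q + anchors$len - 1
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (!length(idx)) next
    idx <- idx[order(anchors$r[idx])]
    ok <- TRUE
    if (length(idx) > 1) {
      for (t in 2:length(idx)) {
        if (!(re[idx[t - 1]] < anchors$r[idx[t]] && qe[idx[t - 1]] < anchors$q[idx[t]])) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, sum(anchors$len[idx]))
  }
  best
}

# literal transcription of the conserved-block rules, applied step by step
gblocks_oracle <- function(mat, min_conserved_frac = 0.5 + 1e-9,
                           min_flank_frac = 0.85, max_nonconserved_run = 8,
                           min_block_len = 5, max_gap_frac = 0.5) {
  n <- nrow(mat); L <- ncol(mat)
  gap_frac <- colMeans(mat == "-")
  topfreq <- sapply(seq_len(L), function(j) {
    col <- mat[, j][mat[, j] != "-"]
    if (!length(col)) 0 else max(table(col)) / n
  })
  good <- gap_frac <= max_gap_frac
  conserved <- good & topfreq >= min_conserved_frac
  highly <- good & topfreq >= min_flank_frac
  keep <- good
  run <- 0
  # walk columns, deleting non-conserved runs longer than the cap
  j <- 1
  while (j <= L) {
    if (good[j] && !conserved[j]) {
      start <- j
      while (j <= L && good[j] && !conserved[j]) j <- j + 1
      if (j - start > max_nonconserved_run) keep[start:(j - 1)] <- FALSE
    } else j <- j + 1
  }
  kept <- integer(0)
  j <- 1
  while (j <= L) {
    if (keep[j]) {
      start <- j
      while (j <= L && keep[j]) j <- j + 1
      block <- start:(j - 1)
      hc <- which(highly[block])
      if (length(hc)) {
        block <- block[min(hc):max(hc)]
        if (length(block) >= min_block_len) kept <- c(kept, block)
      }
    } else j <- j + 1
  }
  kept
}

random_protein <- function(n, seed = NULL) {
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(aas, v[p]), 1)
  paste(v, collapse = "")
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
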