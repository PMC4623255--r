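# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# base -> the three alternative bases, for substitution draws
BASE_ALTERNATIVES <- list(
  A = c("C", "G", "T"),
  C = c("A", "G", "T"),
  G = c("A", "C", "T"),
  T = c("A", "C", "G")
)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

paste_chars <- function(x) paste(x, collapse = "")

#' @importFrom rlang %||% abort warn
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 1-based positions at which two equal-length sequences differ
mismatch_sites <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  which(charToRaw(a) != charToRaw(b))
}

split_codons <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Translate an in-frame CDS; internal stops become 'X' (pseudogene-tolerant),
# a trailing stop is dropped.
translate_cds <- function(nt) {
  n <- nchar(nt)
  if (n %% 3 != 0) abort("CDS length not divisible by 3")
  aa <- unname(Biostrings::GENETIC_CODE[split_codons(nt)])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  aa[aa == "*"] <- "X"
  paste(aa, collapse = "")
}

# JC69 expected observed-difference fraction at distance d (subs/site)
jc_expected_p <- function(d) 0.75 * (1 - exp(-4 * d / 3))
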