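#' Build a random ancestral genome
#'
#' Constructs a single-contig genome with non-overlapping CDS and tRNA
#' features on both strands, separated by random intergenic spacers. Every
#' CDS starts with ATG, ends with a stop codon and contains no internal stop;
#' gene labels (`gene_0001`, ...) are inherited unchanged during evolution
#' and serve as orthology ground truth.
#'
#' @param genome_length Contig length in bp.
#' @param n_genes Number of CDS features.
#' @param gene_length CDS length in bp (divisible by 3).
#' @param n_trna Number of tRNA features.
#' @param trna_length tRNA length in bp.
#' @param gc_content Target GC fraction.
#' @param seed Integer seed.
#' @param genome_id Genome name.
#' @return A [new_genome()] object.
#' @export
build_ancestral_genome <- function(genome_length = 200000, n_genes = 150,
                                   gene_length = 900, n_trna = 4,
                                   trna_length = 76, gc_content = 0.5,
                                   seed, genome_id = "ancestor") {
  if (genome_length < 0 || n_genes < 0 || n_trna < 0) abort("counts must be >= 0")
  if (gene_length %% 3 != 0) abort("gene_length must be divisible by 3")
  if (n_genes > 0 && gene_length < 9) abort("gene_length too short for start + codon + stop")
  used <- n_genes * gene_length + n_trna * trna_length
  if (used > genome_length) abort("features do not fit in genome_length")
  with_seed(seed, {
    ids <- c(
      if (n_genes) sprintf("gene_%04d", seq_len(n_genes)),
      if (n_trna) sprintf("trna_%02d", seq_len(n_trna))
    )
    types <- c(rep("CDS", n_genes), rep("tRNA", n_trna))
    ord <- sample.int(length(ids))
    ids <- ids[ord]; types <- types[ord]
    k <- length(ids)
    gaps <- as.integer(stats::rmultinom(1, genome_length - used, rep(1, k + 1)))
    pieces <- character(2 * k + 1)
    feats <- vector("list", k)
    pos <- 0L
    pieces[1] <- random_dna(gaps[1], gc_content); pos <- pos + gaps[1]
    for (i in seq_len(k)) {
      len <- if (types[i] == "CDS") gene_length else trna_length
      strand <- sample(c("+", "-"), 1)
      s <- if (types[i] == "CDS") random_cds(len, gc_content) else random_dna(len, gc_content)
      genomic <- if (types[i] == "CDS" && strand == "-") revcomp(s) else s
      feats[[i]] <- tibble::tibble(
        contig = "chr", type = types[i],
        start = pos + 1L, end = pos + len, strand = strand,
        feature_id = ids[i], gene = ids[i],
        product = if (types[i] == "CDS") "hypothetical protein" else "tRNA",
        island = FALSE
      )
      pieces[2 * i] <- genomic
      pos <- pos + len
      pieces[2 * i + 1] <- random_dna(gaps[i + 1], gc_content)
      pos <- pos + gaps[i + 1]
    }
    contig <- paste(pieces, collapse = "")
    features <- if (k) dplyr::bind_rows(feats) else empty_features()
    new_genome(genome_id, c(chr = contig), features)
  })
}

# ATG + random non-stop codons + one stop codon, biased toward gc_content
random_cds <- function(len, gc = 0.5) {
  n_codons <- len / 3 - 2
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draw <- function(n) {
    paste0(
      sample(DNA_BASES, n, replace = TRUE, prob = p),
      sample(DNA_BASES, n, replace = TRUE, prob = p),
      sample(DNA_BASES, n, replace = TRUE, prob = p)
    )
  }
  body <- draw(n_codons)
  bad <- which(body %in% STOP_CODONS)
  while (length(bad)) {
    body[bad] <- draw(length(bad))
    bad <- which(body %in% STOP_CODONS)
  }
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}
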