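#' Genome objects
#'
#' A `gi_genome` bundles one or more nucleotide contigs with a typed feature
#' table. It is the universal input record of the package: the simulator
#' emits them, and the orthology, island-delineation and SNP modules consume
#' them. Coordinates are 1-based inclusive (GFF convention) throughout the R
#' API; BED output is converted to 0-based half-open on write.
#'
#' @param genome_id Single string naming the genome (strain).
#' @param contigs Named character vector of upper-case DNA sequences.
#' @param features Feature table, see [empty_features()] for the schema.
#' @return A `gi_genome` object.
#' @export
new_genome <- function(genome_id, contigs, features = empty_features()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1)
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == "")) {
    abort("contigs must be a named character vector")
  }
  features <- tibble::as_tibble(features)
  g <- structure(
    list(genome_id = genome_id, contigs = contigs, features = features),
    class = "gi_genome"
  )
  validate_genome(g)
}

#' Empty feature table with the canonical schema
#'
#' Columns: `contig`, `type` (CDS, tRNA or mobile_genetic_element), `start`,
#' `end` (1-based inclusive), `strand` (`+`/`-`), `feature_id`, `gene`
#' (ortholog label), `product` (free-text annotation) and `island` (logical
#' flag set by the simulator on planted island features).
#'
#' @return A zero-row tibble.
#' @export
empty_features <- function() {
  tibble::tibble(
    contig = character(), type = character(),
    start = integer(), end = integer(), strand = character(),
    feature_id = character(), gene = character(), product = character(),
    island = logical()
  )
}

validate_genome <- function(g) {
  f <- g$features
  need <- names(empty_features())
  missing <- setdiff(need, names(f))
  if (length(missing)) abort(paste("feature table missing columns:", paste(missing, collapse = ", ")))
  if (nrow(f)) {
    if (!all(f$contig %in% names(g$contigs))) abort("feature on unknown contig")
    len <- nchar(g$contigs)[f$contig]
    if (any(f$start < 1 | f$end > len | f$start > f$end)) abort("feature outside contig bounds")
    if (anyDuplicated(f$feature_id)) abort("duplicate feature_id")
    if (!all(f$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  }
  g
}

#' @export
print.gi_genome <- function(x, ...) {
  cat(sprintf(
    "<gi_genome> %s: %d contig(s), %s bp, %d CDS, %d tRNA\n",
    x$genome_id, length(x$contigs),
    format(sum(nchar(x$contigs)), big.mark = ","),
    sum(x$features$type == "CDS"), sum(x$features$type == "tRNA")
  ))
  invisible(x)
}

#' Total genome length in bp
#' @param genome A `gi_genome`.
#' @export
genome_length <- function(genome) sum(nchar(genome$contigs))

#' Feature table of a genome as a tibble
#' @param genome A `gi_genome`.
#' @export
genome_features <- function(genome) genome$features

#' Strand-aware nucleotide sequence of one feature
#' @param genome A `gi_genome`.
#' @param feature_id Feature identifier.
#' @export
feature_seq <- function(genome, feature_id) {
  f <- genome$features[genome$features$feature_id == feature_id, ]
  if (nrow(f) != 1) abort(paste("feature not found:", feature_id))
  s <- substr(genome$contigs[[f$contig]], f$start, f$end)
  if (f$strand == "-") s <- revcomp(s)
  s
}

#' Derive the proteome of a genome
#'
#' Translates every CDS feature (strand-aware, standard code). Internal stop
#' codons -- e.g. in pseudogenes -- are rendered as `X` so downstream
#' alignment still works; the terminal stop is dropped.
#'
#' @param genome A `gi_genome`.
#' @return Tibble with one row per protein: `genome_id`, `gene_id`, `gene`,
#'   `seq`, `contig`, `start`, `end`, `strand`.
#' @export
proteome <- function(genome) {
  cds <- dplyr::filter(genome$features, .data$type == "CDS")
  seqs <- purrr::map_chr(cds$feature_id, function(id) translate_cds(feature_seq(genome, id)))
  tibble::tibble(
    genome_id = genome$genome_id,
    gene_id = cds$feature_id,
    gene = cds$gene,
    seq = seqs,
    contig = cds$contig, start = cds$start, end = cds$end, strand = cds$strand
  )
}

trna_features <- function(genome) {
  dplyr::arrange(dplyr::filter(genome$features, .data$type == "tRNA"), .data$contig, .data$start)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

#' Write a genome as FASTA + GFF3
#'
#' FASTA is wrapped at 80 columns; GFF3 uses 1-based inclusive coordinates
#' with `ID`, `Name`, `product` and `island` attributes.
#'
#' @param genome A `gi_genome`.
#' @param fasta,gff Output paths.
#' @export
write_genome <- function(genome, fasta, gff) {
  dna <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dna, fasta, width = 80L)
  f <- genome$features
  attrs <- paste0(
    "ID=", gff3_escape(f$feature_id),
    ";Name=", gff3_escape(f$gene),
    ";product=", gff3_escape(f$product),
    ifelse(f$island, ";island=true", "")
  )
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", names(genome$contigs), nchar(genome$contigs)),
    if (nrow(f)) paste(f$contig, "islescan", f$type, f$start, f$end, ".", f$strand, ".", attrs, sep = "\t")
  )
  writeLines(lines, gff)
  invisible(c(fasta = fasta, gff = gff))
}

#' Read a genome from FASTA + GFF3
#'
#' @param fasta,gff Input paths.
#' @param genome_id Genome name; defaults to the FASTA basename.
#' @return A `gi_genome`.
#' @export
read_genome <- function(fasta, gff, genome_id = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  names(dna) <- sub("\\s.*$", "", names(dna))
  contigs <- as.character(dna)
  gr <- rtracklayer::import(gff, format = "gff3")
  md <- S4Vectors::mcols(gr)
  pick <- function(col, default) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      v[is.na(v)] <- default
      v
    } else rep(default, length(gr))
  }
  features <- tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    feature_id = pick("ID", NA_character_),
    gene = pick("Name", NA_character_),
    product = pick("product", ""),
    island = tolower(pick("island", "false")) == "true"
  )
  features$feature_id[is.na(features$feature_id)] <-
    paste0("feat_", seq_len(sum(is.na(features$feature_id))))
  if (is.null(genome_id)) genome_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta))
  new_genome(genome_id, contigs, features)
}
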