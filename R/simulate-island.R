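#' Build a genomic-island template
#'
#' Constructs the sequence and gene roster of a mobile island prior to
#' insertion. The roster always contains the two anchor genes (a
#' perchlorate-reductase-like `pcrA` and a chlorite-dismutase-like `cld`,
#' each exactly once) plus a site-specific recombinase; optional mobility
#' markers add conjugation/replication genes (ICE-like cargo) or flanking
#' transposase genes.
#'
#' @param island_length Total template length in bp (excluding the
#'   target-site duplication added at insertion).
#' @param n_genes Number of island genes including anchors and recombinase.
#' @param gene_length CDS length in bp (divisible by 3).
#' @param repeat_length Length of the direct repeat duplicated at insertion
#'   (default 48 bp, the length of the duplicated tRNA segment).
#' @param mobility_markers Character subset of
#'   `c("recombinase", "conjugation", "insertion_sequence")`.
#' @param gc_content Target GC fraction.
#' @param seed Integer seed.
#' @return A `gi_island_template`: list with `seq`, `features` (coordinates
#'   relative to the template, 1-based), `length`, `repeat_length`.
#' @export
build_island_template <- function(island_length = 30000, n_genes = 25,
                                  gene_length = 900, repeat_length = 48,
                                  mobility_markers = "recombinase",
                                  gc_content = 0.5, seed) {
  if (repeat_length < 1) abort("repeat_length must be >= 1")
  bad <- setdiff(mobility_markers, c("recombinase", "conjugation", "insertion_sequence"))
  if (length(bad)) abort(paste("unknown mobility markers:", paste(bad, collapse = ", ")))
  roster <- island_gene_roster(n_genes, mobility_markers)
  if (n_genes * gene_length + 2 > island_length) abort("island genes do not fit in island_length")
  with_seed(seed, {
    k <- nrow(roster)
    gaps <- as.integer(stats::rmultinom(1, island_length - k * gene_length, rep(1, k + 1)))
    # keep at least one spacer base at each template end (junction handling)
    for (side in c(1L, k + 1L)) {
      if (gaps[side] == 0L) {
        donor <- which.max(gaps)
        gaps[donor] <- gaps[donor] - 1L
        gaps[side] <- 1L
      }
    }
    pieces <- character(2 * k + 1)
    feats <- vector("list", k)
    pos <- 0L
    pieces[1] <- random_dna(gaps[1], gc_content); pos <- pos + gaps[1]
    for (i in seq_len(k)) {
      strand <- sample(c("+", "-"), 1)
      s <- random_cds(gene_length, gc_content)
      genomic <- if (strand == "-") revcomp(s) else s
      feats[[i]] <- tibble::tibble(
        contig = "island", type = "CDS",
        start = pos + 1L, end = pos + gene_length, strand = strand,
        feature_id = roster$gene[i], gene = roster$gene[i],
        product = roster$product[i], island = TRUE
      )
      pieces[2 * i] <- genomic
      pos <- pos + gene_length
      pieces[2 * i + 1] <- random_dna(gaps[i + 1], gc_content)
      pos <- pos + gaps[i + 1]
    }
    structure(
      list(
        seq = paste(pieces, collapse = ""),
        features = dplyr::bind_rows(feats),
        length = island_length,
        repeat_length = as.integer(repeat_length)
      ),
      class = "gi_island_template"
    )
  })
}

island_gene_roster <- function(n_genes, mobility_markers) {
  core <- tibble::tibble(
    gene = c("pcrA", "pcrB", "pcrC", "pcrD", "cld"),
    product = c(
      "perchlorate reductase alpha subunit PcrA",
      "perchlorate reductase beta subunit PcrB",
      "perchlorate reductase cytochrome subunit PcrC",
      "perchlorate reductase chaperone PcrD",
      "chlorite dismutase Cld"
    )
  )
  extra <- list()
  if ("recombinase" %in% mobility_markers) {
    extra <- c(extra, list(tibble::tibble(
      gene = "xerD_like", product = "site-specific recombinase XerD"
    )))
  }
  if ("conjugation" %in% mobility_markers) {
    extra <- c(extra, list(tibble::tibble(
      gene = c("traB", "trbE", "repA"),
      product = c(
        "conjugal transfer protein TraB",
        "conjugal transfer protein TrbE",
        "plasmid replication initiator RepA"
      )
    )))
  }
  if ("insertion_sequence" %in% mobility_markers) {
    extra <- c(extra, list(tibble::tibble(
      gene = c("tnpA1", "tnpA2"),
      product = rep("IS element transposase", 2)
    )))
  }
  roster <- dplyr::bind_rows(c(list(core), extra))
  n_fill <- n_genes - nrow(roster)
  if (n_fill < 0) abort("n_genes too small for the requested roster")
  if (n_fill > 0) {
    roster <- dplyr::bind_rows(roster, tibble::tibble(
      gene = sprintf("isl_%03d", seq_len(n_fill)),
      product = "island hypothetical protein"
    ))
  }
  # anchors first and last-ish: shuffle interior, keep pcrA/cld near the start
  roster
}

#' Insert an island at a tRNA integration site
#'
#' Models site-specific integration: the island is placed immediately 3' of
#' the target tRNA and the terminal `repeat_length` bases of the tRNA are
#' duplicated at the island's distal end, creating the pair of flanking
#' direct repeats that the delineation module later detects. The island
#' span recorded in the feature table runs from the base after the proximal
#' repeat copy (i.e. after the intact tRNA) to the end of the distal copy.
#'
#' @param genome A `gi_genome`.
#' @param island A `gi_island_template`.
#' @param trna_index Which tRNA to target, 1-based, in genome order.
#' @return The genome with the island integrated; feature table gains the
#'   island genes plus a `mobile_genetic_element` feature spanning the
#'   island, and an attribute-free truth row is recoverable from that span.
#' @export
insert_island <- function(genome, island, trna_index = 1) {
  trnas <- trna_features(genome)
  if (trna_index < 1 || trna_index > nrow(trnas)) {
    abort(sprintf("no tRNA at index %d (genome has %d)", trna_index, nrow(trnas)))
  }
  t <- trnas[trna_index, ]
  rl <- island$repeat_length
  if (t$end - t$start + 1 < rl) abort("tRNA shorter than repeat_length")
  contig <- genome$contigs[[t$contig]]
  te <- t$end
  rep_seq <- substr(contig, te - rl + 1, te)
  island_seq <- island$seq
  # Disambiguate the integration junctions: if a base flanking a repeat copy
  # happened to match, the maximal repeat would exceed the target-site
  # duplication and the island boundary would be ill-defined. The first and
  # last island bases are intergenic spacer, so they can be rewritten.
  nb <- if (te < nchar(contig)) substr(contig, te + 1, te + 1) else NA_character_
  if (!is.na(nb) && substr(island_seq, 1, 1) == nb) {
    substr(island_seq, 1, 1) <- setdiff(DNA_BASES, nb)[1]
  }
  pb <- if (te - rl >= 1) substr(contig, te - rl, te - rl) else NA_character_
  li <- nchar(island_seq)
  if (!is.na(pb) && substr(island_seq, li, li) == pb) {
    substr(island_seq, li, li) <- setdiff(DNA_BASES, pb)[1]
  }
  ins_len <- nchar(island_seq) + rl
  genome$contigs[[t$contig]] <- paste0(
    substr(contig, 1, te), island_seq, rep_seq,
    substr(contig, te + 1, nchar(contig))
  )
  f <- genome$features
  downstream <- f$contig == t$contig & f$start > te
  f$start[downstream] <- f$start[downstream] + ins_len
  f$end[downstream] <- f$end[downstream] + ins_len
  isl_feats <- island$features
  isl_feats$contig <- t$contig
  isl_feats$start <- isl_feats$start + te
  isl_feats$end <- isl_feats$end + te
  mge <- tibble::tibble(
    contig = t$contig, type = "mobile_genetic_element",
    start = te + 1L, end = te + ins_len, strand = "+",
    feature_id = paste0("island_", genome$genome_id),
    gene = "genomic_island", product = "genomic island", island = TRUE
  )
  genome$features <- dplyr::arrange(
    dplyr::bind_rows(f, isl_feats, mge),
    .data$contig, .data$start, .data$end
  )
  validate_genome(genome)
}

#' The island interval of a genome
#'
#' Reads the `mobile_genetic_element` feature planted by [insert_island()];
#' `NULL` when the genome carries no island.
#'
#' @param genome A `gi_genome`.
#' @return One-row tibble (`contig`, `start`, `end`, `feature_id`) or `NULL`.
#' @export
island_span <- function(genome) {
  m <- dplyr::filter(genome$features, .data$type == "mobile_genetic_element")
  if (!nrow(m)) return(NULL)
  m[, c("contig", "start", "end", "feature_id")]
}

#' Horizontal transfer of an island between extant genomes
#'
#' Copies the island sequence (without its distal repeat copy) from a donor
#' genome, lets it accrue `residual_depth` expected substitutions per site --
#' the divergence since the transfer event -- and integrates it into the
#' recipient at one of its tRNAs, duplicating the recipient's own target
#' site. Donor and recipient islands therefore differ only by substitutions
#' accrued since the event.
#'
#' @param donor,recipient `gi_genome`s; the donor must carry an island.
#' @param trna_index Recipient tRNA to target (1-based).
#' @param residual_depth Expected substitutions/site since the transfer.
#' @param seed Integer seed.
#' @param replace If `TRUE`, an island already present in the recipient is
#'   removed first; otherwise that situation is an error.
#' @return List with `genome` (updated recipient) and `event` (one-row
#'   tibble suitable for an event log).
#' @export
apply_hgt_event <- function(donor, recipient, trna_index = 1,
                            residual_depth = 0, seed, replace = FALSE) {
  span <- island_span(donor)
  if (is.null(span)) abort("donor carries no island")
  if (!is.null(island_span(recipient))) {
    if (!replace) abort("recipient already carries an island")
    recipient <- remove_island(recipient)
  }
  rl <- attr(donor, "repeat_length") %||% 48L
  seq0 <- substr(donor$contigs[[span$contig]], span$start, span$end - rl)
  mut <- mutate_sequence_jc(seq0, residual_depth, seed)
  feats <- dplyr::filter(
    donor$features,
    .data$island, .data$type == "CDS",
    .data$start >= span$start, .data$end <= span$end
  )
  feats$start <- feats$start - span$start + 1L
  feats$end <- feats$end - span$start + 1L
  feats$contig <- "island"
  tpl <- structure(
    list(seq = mut$seq, features = feats, length = nchar(mut$seq), repeat_length = rl),
    class = "gi_island_template"
  )
  out <- insert_island(recipient, tpl, trna_index)
  event <- tibble::tibble(
    type = "transfer", time = residual_depth,
    donor = donor$genome_id, recipient = recipient$genome_id,
    payload = span$feature_id
  )
  list(genome = out, event = event)
}

remove_island <- function(genome) {
  span <- island_span(genome)
  if (is.null(span)) return(genome)
  contig <- genome$contigs[[span$contig]]
  genome$contigs[[span$contig]] <- paste0(
    substr(contig, 1, span$start - 1), substr(contig, span$end + 1, nchar(contig))
  )
  len <- span$end - span$start + 1L
  f <- genome$features
  drop <- f$contig == span$contig & f$start >= span$start & f$end <= span$end
  f <- f[!drop, ]
  downstream <- f$contig == span$contig & f$start > span$end
  f$start[downstream] <- f$start[downstream] - len
  f$end[downstream] <- f$end[downstream] - len
  genome$features <- f
  validate_genome(genome)
}

#' Pseudogenize a CDS by a single point mutation
#'
#' Two inactivation modes: `start_loss` mutates one base of the initiator
#' codon so it is no longer a recognised start (ATG/GTG/TTG); `nonsense`
#' converts one internal codon into a stop by a single base change. Exactly
#' one genomic base changes in either mode.
#'
#' @param genome A `gi_genome`.
#' @param gene_id CDS feature id.
#' @param mode `"start_loss"` or `"nonsense"`.
#' @param seed Integer seed.
#' @return List with `genome` (mutated) and `change` (one-row tibble:
#'   `gene_id`, `mode`, `contig`, `site`, `from`, `to`).
#' @export
apply_pseudogenization <- function(genome, gene_id, mode = c("start_loss", "nonsense"), seed) {
  mode <- match.arg(mode)
  f <- genome$features[genome$features$feature_id == gene_id & genome$features$type == "CDS", ]
  if (nrow(f) != 1) abort(paste("CDS not found:", gene_id))
  cds <- feature_seq(genome, gene_id)
  n_codons <- nchar(cds) / 3
  with_seed(seed, {
    if (mode == "start_loss") {
      hit <- mutate_codon_to(substr(cds, 1, 3), avoid = START_CODONS)
      if (is.null(hit)) abort("cannot break start codon by one substitution")
      cds_pos <- hit$pos
    } else {
      if (n_codons <= 2) abort("no internal codon available for a nonsense mutation")
      internal <- sample(2:(n_codons - 1))
      hit <- NULL
      for (ci in internal) {
        cod <- substr(cds, 3 * ci - 2, 3 * ci)
        hit <- mutate_codon_to(cod, target = STOP_CODONS)
        if (!is.null(hit)) { cds_pos <- 3 * (ci - 1) + hit$pos; break }
      }
      if (is.null(hit)) abort("no single-base nonsense mutation possible")
    }
    # map CDS position to genomic coordinates, strand-aware
    if (f$strand == "+") {
      gpos <- f$start + cds_pos - 1L
      gbase <- hit$to
    } else {
      gpos <- f$end - cds_pos + 1L
      gbase <- chartr("ACGT", "TGCA", hit$to)
    }
    contig <- genome$contigs[[f$contig]]
    from <- substr(contig, gpos, gpos)
    substr(contig, gpos, gpos) <- gbase
    genome$contigs[[f$contig]] <- contig
    genome <- validate_genome(genome)
    list(
      genome = genome,
      change = tibble::tibble(
        gene_id = gene_id, mode = mode, contig = f$contig,
        site = as.integer(gpos), from = from, to = gbase
      )
    )
  })
}

# Random single-base codon edit; either avoiding a codon set or reaching one.
# Returns list(pos (1-3), to (new base at pos), codon) or NULL.
mutate_codon_to <- function(codon, avoid = NULL, target = NULL) {
  v <- chars(codon)
  cand <- list()
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, v[pos])) {
      w <- v; w[pos] <- b
      new <- paste_chars(w)
      ok <- if (!is.null(target)) new %in% target else !(new %in% avoid)
      if (ok) cand[[length(cand) + 1]] <- list(pos = pos, to = b, codon = new)
    }
  }
  if (!length(cand)) return(NULL)
  cand[[sample.int(length(cand), 1)]]
}

#' Tandem-duplicate a gene within a genome
#'
#' Appends an identical copy of a CDS immediately after the original,
#' creating an in-genome paralog. Used to exercise the single-copy-complete
#' orthology filter.
#'
#' @param genome A `gi_genome`.
#' @param gene_id CDS feature id.
#' @return Updated genome; the copy gets feature id `<gene_id>_dup` (same
#'   `gene` label, so truth-based scoring can see it is a paralog).
#' @export
duplicate_gene <- function(genome, gene_id) {
  f <- genome$features[genome$features$feature_id == gene_id & genome$features$type == "CDS", ]
  if (nrow(f) != 1) abort(paste("CDS not found:", gene_id))
  contig <- genome$contigs[[f$contig]]
  seg <- substr(contig, f$start, f$end)
  len <- nchar(seg)
  genome$contigs[[f$contig]] <- paste0(
    substr(contig, 1, f$end), seg, substr(contig, f$end + 1, nchar(contig))
  )
  feats <- genome$features
  downstream <- feats$contig == f$contig & feats$start > f$end
  feats$start[downstream] <- feats$start[downstream] + len
  feats$end[downstream] <- feats$end[downstream] + len
  copy <- f
  copy$feature_id <- paste0(gene_id, "_dup")
  copy$start <- f$end + 1L
  copy$end <- f$end + len
  genome$features <- dplyr::arrange(
    dplyr::bind_rows(feats, copy), .data$contig, .data$start, .data$end
  )
  validate_genome(genome)
}
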