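#' Simulate a clade of genomes with a planted island
#'
#' End-to-end forward simulation of the study design the package is built to
#' analyse: a small genus of carrier strains plus a non-carrier relative, all
#' descending from one ancestor, with a genomic island integrated at a shared
#' tRNA site. Two transfer histories are supported:
#'
#' * `"recent_transfer"`: backbone genomes diverge along the species tree
#'   (pairwise divergence set by `backbone_depth`), then each carrier
#'   acquires the island independently and recently -- every carrier's copy
#'   is the donor island evolved only `island_residual` substitutions/site,
#'   so island divergence is decoupled from (and far below) backbone
#'   divergence.
#' * `"vertical"`: the island is inserted into the common ancestor before
#'   divergence, so island and backbone accumulate substitutions at the same
#'   rate and every leaf carries it.
#'
#' Defaults emulate the statistical structure of a sequenced perchlorate-
#' reducer genus: 3 carriers + 1 non-carrier, ~2% maximal backbone
#' divergence, ~0.01% island divergence, a 48-bp duplicated target site.
#'
#' @param scenario `"recent_transfer"` or `"vertical"`.
#' @param n_carriers,n_relatives Carrier and non-carrier leaf counts.
#' @param genome_length,n_genes,gene_length,n_trna,trna_length,gc_content
#'   Ancestral genome parameters, see [build_ancestral_genome()].
#' @param island_length,island_genes Island template parameters.
#' @param backbone_depth Root-to-tip depth in expected substitutions/site
#'   (maximal pairwise backbone divergence is twice this).
#' @param island_residual Island divergence accrued since each transfer
#'   (recent_transfer only).
#' @param trna_index Shared integration site, 1-based tRNA index.
#' @param n_pseudogenes Number of island genes to pseudogenize in the first
#'   carrier.
#' @param mobility_markers Passed to [build_island_template()].
#' @param seed Integer seed; all stage seeds are derived from it.
#' @return A `gi_simulation`: list with `genomes` (named list of
#'   `gi_genome`), `tree`, `carriers`, `truth` (islands, event log,
#'   per-branch substitution events, pseudogenes) and `params`.
#' @export
simulate_clade <- function(scenario = c("recent_transfer", "vertical"),
                           n_carriers = 3, n_relatives = 1,
                           genome_length = 200000, n_genes = 150,
                           gene_length = 900, n_trna = 4, trna_length = 76,
                           gc_content = 0.5,
                           island_length = 30000, island_genes = 25,
                           backbone_depth = 0.01, island_residual = 5e-5,
                           trna_index = 2, n_pseudogenes = 0,
                           mobility_markers = "recombinase", seed) {
  scenario <- match.arg(scenario)
  if (n_carriers < 1) abort("need at least one carrier")
  n_taxa <- n_carriers + n_relatives
  if (n_taxa < 2) abort("need at least two taxa")
  sseed <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 8 + n_carriers))
  tree <- sample_species_tree(n_taxa, backbone_depth, sseed[1])
  anc <- build_ancestral_genome(
    genome_length = genome_length, n_genes = n_genes, gene_length = gene_length,
    n_trna = n_trna, trna_length = trna_length, gc_content = gc_content,
    seed = sseed[2]
  )
  tpl <- build_island_template(
    island_length = island_length, n_genes = island_genes,
    gene_length = gene_length, mobility_markers = mobility_markers,
    gc_content = gc_content, seed = sseed[3]
  )
  carriers <- sort(tree$tip.label)[seq_len(n_carriers)]
  events <- list()
  if (scenario == "vertical") {
    anc <- insert_island(anc, tpl, trna_index)
    ev <- evolve_sequences(tree, anc, sseed[4])
    genomes <- ev$genomes
    carriers <- tree$tip.label
    events[[1]] <- tibble::tibble(
      type = "insertion", time = backbone_depth, donor = "ancestor",
      recipient = "ancestor", payload = "island"
    )
  } else {
    ev <- evolve_sequences(tree, anc, sseed[4])
    genomes <- ev$genomes
    for (i in seq_along(carriers)) {
      ci <- carriers[i]
      mut <- mutate_sequence_jc(tpl$seq, island_residual, sseed[8 + i])
      tpl_i <- tpl
      tpl_i$seq <- mut$seq
      genomes[[ci]] <- insert_island(genomes[[ci]], tpl_i, trna_index)
      events[[length(events) + 1]] <- tibble::tibble(
        type = "transfer", time = island_residual, donor = "donor_lineage",
        recipient = ci, payload = "island"
      )
    }
  }
  pseudo <- NULL
  if (n_pseudogenes > 0) {
    target <- carriers[1]
    isl_genes <- dplyr::filter(
      genomes[[target]]$features,
      .data$island, .data$type == "CDS",
      !.data$gene %in% c("pcrA", "cld")
    )$feature_id
    picks <- with_seed(sseed[5], sample(isl_genes, min(n_pseudogenes, length(isl_genes))))
    modes <- with_seed(sseed[6], sample(c("start_loss", "nonsense"), length(picks), replace = TRUE))
    ch <- vector("list", length(picks))
    for (j in seq_along(picks)) {
      res <- apply_pseudogenization(genomes[[target]], picks[j], modes[j], seed = sseed[7] + j)
      genomes[[target]] <- res$genome
      ch[[j]] <- dplyr::mutate(res$change, genome_id = target)
      events[[length(events) + 1]] <- tibble::tibble(
        type = "pseudogenization", time = 0, donor = target,
        recipient = target, payload = picks[j]
      )
    }
    pseudo <- dplyr::bind_rows(ch)
  }
  islands <- dplyr::bind_rows(lapply(carriers, function(id) {
    sp <- island_span(genomes[[id]])
    if (is.null(sp)) return(NULL)
    tibble::tibble(
      genome_id = id, contig = sp$contig, start = sp$start, end = sp$end,
      repeat_length = tpl$repeat_length, trna_index = trna_index
    )
  }))
  structure(
    list(
      genomes = genomes, tree = tree, carriers = carriers,
      truth = list(
        islands = islands,
        events = dplyr::bind_rows(events),
        substitutions = ev$events,
        pseudogenes = pseudo
      ),
      params = list(
        scenario = scenario, genome_length = genome_length,
        island_length = island_length, backbone_depth = backbone_depth,
        island_residual = island_residual, trna_index = trna_index,
        repeat_length = tpl$repeat_length, seed = seed
      )
    ),
    class = "gi_simulation"
  )
}

#' @export
print.gi_simulation <- function(x, ...) {
  cat(sprintf(
    "<gi_simulation> %s: %d genomes (%d carriers), backbone depth %g, island %s bp\n",
    x$params$scenario, length(x$genomes), length(x$carriers),
    x$params$backbone_depth,
    format(x$params$island_length, big.mark = ",")
  ))
  invisible(x)
}

#' Write a simulation and its ground truth to disk
#'
#' Emits per-genome FASTA (80-column) + GFF3, the species tree as Newick,
#' island coordinates as BED6 (0-based half-open), the event log and the
#' per-branch substitution events as TSV. [read_truth_bundle()] reverses it.
#'
#' @param sim A `gi_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
emit_truth_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste("cannot create directory", dir))
  for (g in sim$genomes) {
    write_genome(
      g,
      file.path(dir, paste0(g$genome_id, ".fasta")),
      file.path(dir, paste0(g$genome_id, ".gff3"))
    )
  }
  ape::write.tree(sim$tree, file.path(dir, "species_tree.nwk"))
  isl <- sim$truth$islands
  bed <- tibble::tibble(
    chrom = isl$contig, start = isl$start - 1L, end = isl$end,
    name = isl$genome_id, score = 0L, strand = "+"
  )
  readr::write_tsv(bed, file.path(dir, "islands.bed"), col_names = FALSE)
  readr::write_tsv(sim$truth$events, file.path(dir, "events.tsv"))
  readr::write_tsv(sim$truth$substitutions, file.path(dir, "substitutions.tsv"))
  if (!is.null(sim$truth$pseudogenes)) {
    readr::write_tsv(sim$truth$pseudogenes, file.path(dir, "pseudogenes.tsv"))
  }
  invisible(dir)
}

#' Read back a truth bundle written by [emit_truth_bundle()]
#'
#' @param dir Directory written by [emit_truth_bundle()].
#' @return List with `genomes`, `tree`, `islands` (1-based inclusive),
#'   `events`, `substitutions`.
#' @export
read_truth_bundle <- function(dir) {
  fastas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  genomes <- lapply(fastas, function(fa) {
    id <- sub("\\.fasta$", "", basename(fa))
    read_genome(fa, file.path(dir, paste0(id, ".gff3")), genome_id = id)
  })
  names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1))
  bed_path <- file.path(dir, "islands.bed")
  islands <- if (file.exists(bed_path)) {
    bed <- readr::read_tsv(
      bed_path,
      col_names = c("chrom", "start", "end", "name", "score", "strand"),
      col_types = "ciicic", progress = FALSE
    )
    tibble::tibble(
      genome_id = bed$name, contig = bed$chrom,
      start = bed$start + 1L, end = bed$end
    )
  } else NULL
  list(
    genomes = genomes,
    tree = ape::read.tree(file.path(dir, "species_tree.nwk")),
    islands = islands,
    events = readr::read_tsv(file.path(dir, "events.tsv"), show_col_types = FALSE, progress = FALSE),
    substitutions = readr::read_tsv(file.path(dir, "substitutions.tsv"), show_col_types = FALSE, progress = FALSE)
  )
}
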