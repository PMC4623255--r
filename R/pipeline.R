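default_config <- function() {
  list(
    output_dir = NULL,
    seed = NULL,
    simulate = list(
      scenario = "recent_transfer", n_carriers = 3, n_relatives = 1,
      genome_length = 200000, n_genes = 150, gene_length = 900,
      n_trna = 4, trna_length = 76, gc_content = 0.5,
      island_length = 30000, island_genes = 25,
      backbone_depth = 0.01, island_residual = 5e-5,
      trna_index = 2, n_pseudogenes = 0, mobility_markers = "recombinase"
    ),
    genomes = NULL,
    orthology = list(min_score = 50, min_coverage = 0.5),
    identity_threshold = 0.90,
    mlsa = list(n_reps = 100, trim = TRUE),
    delineate = list(min_len = 40, max_mismatch = 0, min_sep = 5000, max_sep = 200000),
    snp = list(window = 500, min_anchor = 20, max_gap = 5000,
               alpha = 0.01, ratio_cut = 0.1)
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Reads YAML (path or literal text), fills defaults for every module
#' block, rejects unknown keys by name, and enforces that a seed and an
#' output directory are present. Exactly one of `simulate` (simulation
#' mode) or `genomes` (paths to FASTA+GFF3 pairs) drives the input stage.
#'
#' @param config YAML path, YAML text, or a raw list.
#' @return A validated `gi_config` list.
#' @export
validate_config <- function(config) {
  raw <- if (is.list(config)) {
    config
  } else if (length(config) == 1 && file.exists(config)) {
    yaml::read_yaml(config)
  } else {
    yaml::yaml.load(paste(config, collapse = "\n"))
  }
  if (!is.list(raw)) abort("config must be a YAML mapping")
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- def
  for (k in names(raw)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      sub_unknown <- setdiff(names(raw[[k]]), names(def[[k]]))
      if (length(sub_unknown) && k != "genomes") {
        abort(paste0("unknown config key(s) in '", k, "': ", paste(sub_unknown, collapse = ", ")))
      }
      cfg[[k]] <- utils::modifyList(def[[k]], raw[[k]])
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  if (is.null(cfg$output_dir)) abort("config requires output_dir")
  if (is.null(cfg$seed)) abort("config requires an explicit seed")
  if (!is.null(raw$genomes)) cfg$simulate <- NULL
  structure(cfg, class = "gi_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

stage_marker <- function(dir, stage) file.path(dir, paste0(".stage_", stage, ".done"))

stage_done <- function(dir, stage, hash) {
  m <- stage_marker(dir, stage)
  file.exists(m) && identical(readLines(m, n = 1), hash)
}

mark_stage <- function(dir, stage, hash) writeLines(hash, stage_marker(dir, stage))

#' Run the full analysis pipeline
#'
#' simulate (or load) -> orthologs -> supermatrix tree -> island
#' delineation -> SNP scan -> report. Every stage writes plain
#' standard-format files under the configured output directory, records a
#' completion marker keyed by the config hash (so an interrupted run
#' resumes past finished stages), and contributes to the run manifest.
#'
#' @param cfg A `gi_config` from [validate_config()].
#' @return A `gi_manifest`: list with `config_hash`, per-stage `timings`,
#'   `files` (md5 checksums), `warnings`, and in-memory `results`.
#' @export
run_full_pipeline <- function(cfg) {
  if (!inherits(cfg, "gi_config")) cfg <- validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  timings <- list()
  warnings <- character(0)
  results <- list()
  cache_dir <- file.path(cfg$output_dir, ".cache")
  dir.create(cache_dir, showWarnings = FALSE)
  run_stage <- function(stage, fun) {
    cache <- file.path(cache_dir, paste0(stage, ".rds"))
    if (stage_done(cfg$output_dir, stage, hash) && file.exists(cache)) {
      timings[[stage]] <<- 0
      return(readRDS(cache))
    }
    t0 <- Sys.time()
    out <- withCallingHandlers(
      fun(),
      warning = function(w) {
        warnings <<- c(warnings, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    saveRDS(out, cache)
    mark_stage(cfg$output_dir, stage, hash)
    out
  }

  gdir <- file.path(cfg$output_dir, "genomes")
  if (!is.null(cfg$simulate)) {
    sim_fun <- function() {
      sim <- do.call(simulate_clade, c(cfg$simulate, list(seed = cfg$seed)))
      emit_truth_bundle(sim, gdir)
      sim
    }
    sim <- run_stage("simulate", sim_fun)
    genomes <- sim$genomes
    carriers <- sim$carriers
    islands_truth <- sim$truth$islands
  } else {
    load_fun <- function() {
      lapply(cfg$genomes, function(g) read_genome(g$fasta, g$gff, genome_id = g$id))
    }
    genomes <- run_stage("load", load_fun)
    names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1))
    carriers <- names(genomes)
    islands_truth <- NULL
    sim <- NULL
  }
  results$genomes <- genomes

  orth <- run_stage("orthologs", function() {
    o <- orthology_pipeline(genomes, min_score = cfg$orthology$min_score,
                            min_coverage = cfg$orthology$min_coverage)
    write_clusters(o$clusters, file.path(cfg$output_dir, "clusters.tsv"))
    o
  })
  results$orthology <- orth

  results$mlsa <- run_stage("mlsa_tree", function() {
    prots <- dplyr::bind_rows(lapply(genomes, proteome))
    sc <- orth$single_copy |>
      dplyr::left_join(prots[, c("genome_id", "gene_id", "seq")],
                       by = c("genome_id", "gene_id"))
    locus_seqs <- lapply(split(sc, sc$cluster_id), function(d) stats::setNames(d$seq, d$genome_id))
    res <- mlsa_pipeline(locus_seqs, n_reps = cfg$mlsa$n_reps,
                         seed = cfg$seed + 1, trim = cfg$mlsa$trim)
    write_phylip(res$supermatrix, file.path(cfg$output_dir, "supermatrix.phy"))
    write_partitions(res$supermatrix, file.path(cfg$output_dir, "partitions.txt"))
    write_support_tree(res$tree, file.path(cfg$output_dir, "mlsa_tree.nwk"))
    res
  })

  results$islands <- run_stage("delineate", function() {
    calls <- dplyr::bind_rows(lapply(genomes, function(g) {
      dl <- do.call(delineate_islands, c(list(g), cfg$delineate))
      if (!nrow(dl) && nrow(trna_features(g)) == 0) {
        warn(sprintf("genome %s has no tRNA annotations; repeat-only evidence", g$genome_id))
      }
      dl
    }))
    if (nrow(calls)) {
      write_islands_bed(calls, file.path(cfg$output_dir, "islands.bed"))
      mob <- dplyr::bind_rows(lapply(seq_len(nrow(calls)), function(i) {
        classify_mobility(genomes[[calls$genome_id[i]]], calls[i, ])
      }))
      jsonlite::write_json(
        list(calls = dplyr::select(calls, -"gene_ids"), mobility = mob),
        file.path(cfg$output_dir, "island_evidence.json"), auto_unbox = TRUE, digits = NA
      )
      attr(calls, "mobility") <- mob
    }
    calls
  })

  results$snp <- run_stage("snp_scan", function() {
    calls <- results$islands
    ref_id <- carriers[1]
    ref <- genomes[[ref_id]]
    isl <- if (!is.null(calls) && nrow(calls)) {
      c1 <- calls[calls$genome_id == ref_id, ]
      if (nrow(c1)) c1[1, ] else NULL
    } else NULL
    queries <- setdiff(names(genomes), ref_id)
    scans <- lapply(queries, function(q) {
      sc <- tryCatch(
        snp_scan(ref, genomes[[q]], island = isl, window = cfg$snp$window,
                 min_anchor = cfg$snp$min_anchor, max_gap = cfg$snp$max_gap,
                 alpha = cfg$snp$alpha, ratio_cut = cfg$snp$ratio_cut),
        error = function(e) {
          warn(sprintf("snp scan %s vs %s: %s", q, ref_id, conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(sc)) {
        write_snp_vcf(sc$snps, file.path(cfg$output_dir, paste0("snps_", q, ".vcf")),
                      sample_name = q)
        if (!is.null(sc$windows)) {
          write_bedgraph(sc$windows, file.path(cfg$output_dir, paste0("windows_", q, ".bedgraph")))
        }
      }
      sc
    })
    names(scans) <- queries
    scans
  })

  manifest <- list(
    config_hash = hash,
    reference = carriers[1],
    timings = timings,
    warnings = warnings
  )
  report <- write_report(manifest, results, cfg$output_dir)
  files <- list.files(cfg$output_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("\\.stage_|\\.cache/", files)]
  manifest$files <- stats::setNames(as.character(tools::md5sum(files)),
                                    sub(paste0("^", cfg$output_dir, "/?"), "", files))
  manifest$report <- report
  manifest$results <- results
  jsonlite::write_json(
    manifest[c("config_hash", "reference", "timings", "warnings", "files")],
    file.path(cfg$output_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  structure(manifest, class = "gi_manifest")
}

#' Write the divergence report
#'
#' Emits `report.tsv` with one row per query genome and region (island /
#' backbone): SNP count, aligned length, frequency, island/backbone ratio,
#' exact-test p value and acquisition call.
#'
#' @param manifest Manifest under construction (list).
#' @param results Pipeline results list.
#' @param output_dir Output directory.
#' @return The report tibble.
#' @export
write_report <- function(manifest, results, output_dir) {
  scans <- results$snp
  rows <- list()
  for (q in names(scans)) {
    sc <- scans[[q]]
    if (is.null(sc)) next
    if (!is.null(sc$contrast)) {
      ct <- sc$contrast
      rows[[length(rows) + 1]] <- tibble::tibble(
        query = q, region = c("island", "backbone"),
        n_snps = c(ct$island$k, ct$backbone$k),
        aligned_bp = c(ct$island$n, ct$backbone$n),
        frequency = c(ct$island$frequency, ct$backbone$frequency),
        ratio = ct$ratio, p_value = ct$p_value, call = ct$call
      )
    } else {
      n_snps <- nrow(sc$snps)
      aligned_bp <- sum(sc$map$ref_end[sc$map$type == "aligned"] -
                          sc$map$ref_start[sc$map$type == "aligned"] + 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        query = q, region = "genome",
        n_snps = n_snps, aligned_bp = aligned_bp,
        frequency = n_snps / aligned_bp,
        ratio = NA_real_, p_value = NA_real_, call = NA_character_
      )
    }
  }
  report <- dplyr::bind_rows(rows)
  if (nrow(report)) readr::write_tsv(report, file.path(output_dir, "report.tsv"))
  report
}
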