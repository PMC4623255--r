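test_that("planted direct repeats are found with exact coordinates", {
  set.seed(201)
  bg <- random_dna_str(100000)
  unit <- random_dna_str(48)
  contig <- paste0(substr(bg, 1, 9999), unit,
                   substr(bg, 10048, 39999), unit,
                   substr(bg, 40048, 100000))
  # guard the junctions so the planted pair is maximal
  reps <- find_direct_repeats(contig, min_len = 40, min_sep = 5000, max_sep = 200000)
  hit <- reps[reps$length >= 48, ]
  expect_equal(nrow(hit), 1)
  expect_lte(hit$start1, 10000); expect_gte(hit$end1, 10047)
  expect_lte(hit$start2, 40000); expect_gte(hit$end2, 40047)

  expect_error(find_direct_repeats(contig, min_len = 10), "min_len")
  # contig with no long repeat
  expect_equal(nrow(find_direct_repeats(random_dna_str(5000, seed = 1), min_sep = 10, max_sep = 5000)), 0)
})

test_that("repeat finder equals the quadratic brute-force scan", {
  for (s in 1:4) {
    set.seed(300 + s)
    contig <- random_dna_str(2000)
    # plant two repeat families
    u1 <- random_dna_str(60)
    u2 <- random_dna_str(45)
    contig <- paste0(substr(contig, 1, 100), u1,
                     substr(contig, 161, 900), u2,
                     substr(contig, 946, 1200), u1,
                     substr(contig, 1261, 1700), u2,
                     substr(contig, 1746, 2000))
    got <- find_direct_repeats(contig, min_len = 40, max_mismatch = 0,
                               min_sep = 100, max_sep = 2000, k = 16)
    want <- brute_force_repeats(contig, min_len = 40, min_sep = 100, max_sep = 2000)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start1, want$start1)
    expect_equal(got$end1, want$end1)
    expect_equal(got$start2, want$start2)
    expect_equal(got$end2, want$end2)
  }
})

test_that("island calls recover the simulator's planted coordinates exactly", {
  for (s in 1:3) {
    sim <- tiny_clade(400 + s)
    for (cid in sim$carriers) {
      g <- sim$genomes[[cid]]
      calls <- delineate_islands(g, min_sep = 5000, max_sep = 50000)
      truth <- sim$truth$islands[sim$truth$islands$genome_id == cid, ]
      expect_equal(nrow(calls), 1)
      expect_equal(calls$start, truth$start)
      expect_equal(calls$end, truth$end)
      expect_true(calls$ev_repeat && calls$ev_trna)
    }
    # the non-carrier relative yields no call
    rel <- setdiff(names(sim$genomes), sim$carriers)
    expect_equal(nrow(delineate_islands(sim$genomes[[rel]], min_sep = 5000, max_sep = 50000)), 0)
  }
})

test_that("repeat pairs away from tRNAs are reported but not called", {
  g <- build_ancestral_genome(genome_length = 30000, n_genes = 10, gene_length = 600,
                              n_trna = 1, seed = 55)
  # plant a repeat pair far from the tRNA
  trna <- trna_features(g)
  contig <- g$contigs[[1]]
  unit <- random_dna_str(50, seed = 9)
  # choose positions beyond the tRNA interval
  p1 <- if (trna$start > 15000) 500 else 20000
  p2 <- p1 + 8000
  substr(contig, p1, p1 + 49) <- unit
  substr(contig, p2, p2 + 49) <- unit
  g$contigs[[1]] <- contig
  g$features <- g$features[g$features$type == "tRNA", ]  # keep only the tRNA
  calls <- locate_integration_sites(g, find_direct_repeats(contig, min_sep = 5000, max_sep = 20000))
  ua <- attr(calls, "unassigned")
  expect_equal(nrow(calls), 0)
  expect_gte(nrow(ua), 1)
})

test_that("competing repeat pairs at one tRNA resolve to the longer span", {
  contig <- random_dna_str(40000, seed = 66)
  g <- new_genome("two_pairs", c(chr = contig), tibble::tibble(
    contig = "chr", type = "tRNA", start = 1001L, end = 1076L, strand = "+",
    feature_id = "trna_01", gene = "trna_01", product = "tRNA", island = FALSE
  ))
  trna <- trna_features(g)
  # two distal copies of the tRNA's 48-bp suffix at different distances
  suffix <- substr(contig, trna$end - 47, trna$end)
  q1 <- trna$end + 8000; q2 <- trna$end + 20000
  substr(contig, q1, q1 + 47) <- suffix
  substr(contig, q2, q2 + 47) <- suffix
  # break chance junction matches so the planted copies are maximal
  other_than <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  lflank <- substr(contig, trna$end - 48, trna$end - 48)
  rflank <- substr(contig, trna$end + 1, trna$end + 1)
  for (q in c(q1, q2)) {
    substr(contig, q - 1, q - 1) <- other_than(lflank)
    substr(contig, q + 48, q + 48) <- other_than(rflank)
  }
  g$contigs[[1]] <- contig
  calls <- locate_integration_sites(
    g, find_direct_repeats(contig, min_sep = 5000, max_sep = 40000)
  )
  expect_equal(nrow(calls), 1)
  expect_equal(calls$end, q2 + 47)   # longer-spanning pair preferred
  expect_gte(nrow(attr(calls, "candidates")), 2)
})

test_that("flanking synteny distinguishes empty sites from occupied ones", {
  sim <- tiny_clade(77, n_relatives = 1)
  orth <- orthology_pipeline(sim$genomes)
  carrier <- sim$genomes[[sim$carriers[1]]]
  rel_id <- setdiff(names(sim$genomes), sim$carriers)
  rel <- sim$genomes[[rel_id]]
  call <- delineate_islands(carrier, min_sep = 5000, max_sep = 50000)[1, ]

  syn <- flanking_synteny_score(carrier, call, rel, orth$clusters)
  expect_true(syn$contiguous)
  expect_equal(syn$intervening_gene_count, 0L)

  # occupied site: plant a 10-gene element into the relative at the tRNA
  other <- build_island_template(island_length = 9200, n_genes = 10, gene_length = 900,
                                 mobility_markers = character(0), seed = 5)
  other$features$gene <- paste0("alien_", seq_len(nrow(other$features)))
  other$features$feature_id <- other$features$gene
  rel_occupied <- insert_island(rel, other, sim$params$trna_index)
  orth2 <- orthology_pipeline(
    stats::setNames(list(carrier, rel_occupied), c(carrier$genome_id, rel_id))
  )
  syn2 <- flanking_synteny_score(carrier, call, rel_occupied, orth2$clusters)
  expect_false(syn2$contiguous)
  expect_equal(syn2$intervening_gene_count, 10L)
  # threshold monotonicity
  syn3 <- flanking_synteny_score(carrier, call, rel_occupied, orth2$clusters,
                                 gap_tolerance = 10)
  expect_true(syn3$contiguous)
})

test_that("anchor core expansion separates shared core from accessory cargo", {
  # islands {pcrA, cld, x, y} and {pcrA, cld, x, z}
  tab <- tibble::tibble(
    genome_id = c("g1", "g1", "g1", "g1", "g2", "g2", "g2", "g2"),
    gene_id = paste0("f", 1:8),
    cluster_id = c("pcrA", "cld", "x", "y", "pcrA", "cld", "x", "z")
  )
  res <- anchor_core_expansion(tab, anchors = c("pcrA", "cld"))
  expect_setequal(res$core, c("pcrA", "cld", "x"))
  expect_equal(res$accessory$g1, "y")
  expect_equal(res$accessory$g2, "z")

  expect_error(anchor_core_expansion(tab[tab$genome_id == "g1", ], c("pcrA", "cld")),
               "two islands")
  expect_error(anchor_core_expansion(tab, anchors = "absent"), "anchor")

  # interior island-specific run of length 2 (< stop_run) is walked across;
  # brute-force expectation: shared clusters reachable from the anchors
  walk <- tibble::tibble(
    genome_id = rep(c("g1", "g2"), each = 6),
    gene_id = paste0("w", 1:12),
    cluster_id = c("pcrA", "s1", "u1", "u2", "s2", "cld",
                   "pcrA", "s1", "v1", "v2", "s2", "cld")
  )
  res2 <- anchor_core_expansion(walk, anchors = c("pcrA", "cld"), stop_run = 3)
  occ <- table(unique(walk[, c("genome_id", "cluster_id")])$cluster_id)
  brute_core <- names(occ)[occ >= 2]  # all reachable here since runs < stop_run
  expect_setequal(res2$core, brute_core)

  # a run of stop_run island-specific genes blocks the walk
  blocked <- tibble::tibble(
    genome_id = rep(c("g1", "g2"), each = 6),
    gene_id = paste0("b", 1:12),
    cluster_id = c("pcrA", "u1", "u2", "u3", "far", "cld",
                   "pcrA", "v1", "v2", "v3", "far", "cld")
  )
  res3 <- anchor_core_expansion(blocked, anchors = "pcrA", stop_run = 3)
  expect_false("far" %in% res3$core)  # unreachable from pcrA going right
})

test_that("mobility classification recognises the three mechanisms", {
  sim <- tiny_clade(88)
  carrier <- sim$genomes[[sim$carriers[1]]]
  call <- delineate_islands(carrier, min_sep = 5000, max_sep = 50000)[1, ]
  expect_equal(classify_mobility(carrier, call)$class, "trna_integrative")

  # ICE: conjugation + replication markers, no repeat evidence
  ice_g <- build_ancestral_genome(genome_length = 30000, n_genes = 5, gene_length = 600,
                                  n_trna = 1, seed = 91)
  ice_tpl <- build_island_template(island_length = 9200, n_genes = 10, gene_length = 900,
                                   mobility_markers = "conjugation", seed = 92)
  ice_genome <- insert_island(ice_g, ice_tpl, 1)
  sp <- island_span(ice_genome)
  fake_call <- tibble::tibble(contig = sp$contig, start = sp$start, end = sp$end,
                              ev_repeat = FALSE, ev_trna = FALSE)
  res_ice <- classify_mobility(ice_genome, fake_call)
  expect_equal(res_ice$class, "ice")

  # composite transposon: identical 800-bp IS copies flanking the island
  ct <- build_ancestral_genome(genome_length = 30000, n_genes = 5, gene_length = 600,
                               n_trna = 1, seed = 93)
  is_seq <- paste0("ATG", random_dna_str(792, seed = 94), "TAA")
  contig <- ct$contigs[[1]]
  left <- 5000; right <- 18000
  substr(contig, left, left + 799) <- is_seq
  substr(contig, right, right + 799) <- is_seq
  ct$contigs[[1]] <- contig
  ct$features <- dplyr::bind_rows(
    ct$features[0, ],
    tibble::tibble(
      contig = "chr", type = "CDS",
      start = c(left, right), end = c(left + 799L, right + 799L), strand = "+",
      feature_id = c("is1", "is2"), gene = c("tnpA1", "tnpA2"),
      product = "IS element transposase", island = FALSE
    )
  )
  ct_call <- tibble::tibble(contig = "chr", start = left + 800L, end = right - 1L,
                            ev_repeat = FALSE, ev_trna = FALSE)
  expect_equal(classify_mobility(ct, ct_call)$class, "composite_transposon")

  # nothing matching: unknown, and the classifier is total
  plain_call <- tibble::tibble(contig = "chr", start = 100, end = 2000,
                               ev_repeat = FALSE, ev_trna = FALSE)
  expect_equal(classify_mobility(ct, plain_call)$class, "unknown")
})
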