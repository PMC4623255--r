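test_that("anchor chaining aligns identical and substituted sequences completely", {
  s <- random_dna_str(6000, seed = 1)
  map <- anchor_chain_align(s, s)
  aligned <- map[map$type == "aligned", ]
  expect_equal(min(aligned$ref_start), 1)
  expect_equal(max(aligned$ref_end), 6000)
  expect_equal(nrow(call_snps(map)), 0)

  # 10 planted substitutions -> exactly 10 SNPs at exact positions
  v <- strsplit(s, "")[[1]]
  set.seed(2)
  pos <- sort(sample(100:5900, 10))
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  q <- paste(v, collapse = "")
  map2 <- anchor_chain_align(s, q)
  snps <- call_snps(map2)
  expect_equal(snps$pos, pos)
  expect_equal(snps$ref, substring(s, pos, pos))
  expect_equal(snps$alt, substring(q, pos, pos))

  # every reference base assigned exactly once
  cov <- map2[map2$type != "insertion_query", ]
  cov <- cov[order(cov$ref_start), ]
  expect_equal(cov$ref_start[1], 1)
  expect_equal(cov$ref_end[nrow(cov)], 6000)
  if (nrow(cov) > 1) expect_true(all(diff(cov$ref_start) > 0 &
                                       utils::head(cov$ref_end, -1) + 1 == utils::tail(cov$ref_start, -1)))
})

test_that("chain weight equals exhaustive enumeration on random anchors", {
  for (s in 1:4) {
    set.seed(500 + s)
    anchors <- tibble::tibble(
      r = sample(1:900, 12), q = sample(1:900, 12), len = sample(15:40, 12, TRUE)
    )
    got <- islescan:::heaviest_colinear_chain(anchors)
    expect_equal(sum(got$len), brute_force_chain_weight(anchors))
  }
})

test_that("columns with N are skipped in SNP calls", {
  s <- random_dna_str(3000, seed = 7)
  v <- strsplit(s, "")[[1]]
  v[1500] <- "G"
  q <- paste(v, collapse = "")
  sN <- s
  substr(sN, 1500, 1500) <- "N"
  map <- anchor_chain_align(sN, q)
  snps <- call_snps(map)
  expect_false(1500 %in% snps$pos)
})

test_that("window histograms tile, count, and conserve SNPs", {
  snps <- tibble::tibble(pos = c(10L, 400L, 700L))
  tr <- window_snp_histogram(snps, list(start = 1, end = 1000), window = 500)
  expect_equal(tr$n_snps, c(2L, 1L))

  tr0 <- window_snp_histogram(snps[0, ], list(start = 1, end = 1000), window = 500)
  expect_true(all(tr0$n_snps == 0))

  tr3 <- window_snp_histogram(snps, list(start = 1, end = 1250), window = 500)
  expect_equal(tr3$effective_length, c(500L, 500L, 250L))
  expect_equal(sum(tr3$n_snps), 3)
  expect_error(window_snp_histogram(snps, list(start = 1, end = 10), window = 0), "window")
})

test_that("region frequencies use the documented denominators", {
  map <- structure(
    tibble::tibble(
      type = c("aligned", "unaligned_ref"),
      ref_start = c(1L, 501L), ref_end = c(500L, 1000L),
      query_start = c(1L, NA), query_end = c(500L, NA),
      ref_aln = NA_character_, query_aln = NA_character_, contig = "chr"
    ),
    class = c("gi_segment_map", class(tibble::tibble())), contig = "chr", ref_len = 1000L
  )
  snps <- tibble::tibble(pos = c(10L, 20L, 30L, 40L, 50L))
  f <- region_snp_frequency(snps, list(start = 1, end = 1000), map)
  expect_equal(f$freq_aligned, 5 / 500)
  expect_equal(f$freq_total, 5 / 1000)
  expect_equal(f$frequency, 0.01)

  f0 <- region_snp_frequency(snps[0, ], list(start = 1, end = 500), map)
  expect_equal(f0$frequency, 0)

  expect_error(region_snp_frequency(snps, list(start = 501, end = 1000), map),
               "undefined")
})

test_that("the acquisition contrast follows the exact binomial tail", {
  # island 0/1000 against a 1% backbone rate: p = 0.99^1000
  ct <- acquisition_contrast_test(0, 1000, 100, 10000)
  expect_equal(ct$p_value, 0.99^1000, tolerance = 1e-12)
  expect_equal(ct$call, "recent_independent")

  # equal rates: ancestral_vertical
  ct2 <- acquisition_contrast_test(200, 10000, 200, 10000)
  expect_equal(ct2$ratio, 1)
  expect_equal(ct2$call, "ancestral_vertical")

  expect_error(acquisition_contrast_test(0, 100, 0, 1000), "zero")

  # brute-force summation agreement to 1e-12 for n <= 1000
  for (s in 1:5) {
    set.seed(600 + s)
    n1 <- sample(100:1000, 1)
    rate <- stats::runif(1, 0.001, 0.05)
    k1 <- stats::rbinom(1, n1, rate)
    ct3 <- acquisition_contrast_test(k1, n1, round(rate * 1e5), 1e5)
    expect_equal(ct3$p_value, binom_tail_oracle(k1, n1, round(rate * 1e5) / 1e5),
                 tolerance = 1e-12)
  }

  # monotone in k1
  ps <- vapply(0:20, function(k) acquisition_contrast_test(k, 1000, 200, 10000)$p_value,
               numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("tidy/glance/autoplot methods expose the contrast", {
  ct <- acquisition_contrast_test(3, 30000, 600, 30000)
  td <- tidy(ct)
  expect_equal(td$n_snps, c(3, 600))
  gl <- glance(ct)
  expect_equal(gl$call, ct$call)
  expect_s3_class(autoplot(ct), "ggplot")
  tr <- window_snp_histogram(tibble::tibble(pos = c(5L, 600L)), list(start = 1, end = 1000))
  expect_s3_class(autoplot(tr), "ggplot")
})

test_that("coding-effect annotation is strand-aware and codon-exact", {
  # constructed 800-codon gene: residue 431 is Ile (ATT); A->C gives CTT = Leu
  n_codons <- 800
  body <- rep("GCT", n_codons)   # Ala backbone
  body[1] <- "ATG"
  body[431] <- "ATT"
  body[n_codons] <- "TAA"
  cds <- paste(body, collapse = "")
  g <- new_genome("ref", c(chr = paste0(random_dna_str(100, seed = 8), cds, random_dna_str(100, seed = 9))),
                  tibble::tibble(
                    contig = "chr", type = "CDS", start = 101L, end = 100L + 2400L,
                    strand = "+", feature_id = "pcrA", gene = "pcrA",
                    product = "perchlorate reductase alpha subunit PcrA", island = FALSE
                  ))
  pos <- 100L + (431L - 1L) * 3L + 1L
  eff <- annotate_coding_effect(
    tibble::tibble(contig = "chr", pos = pos, ref = "A", alt = "C"), g
  )
  expect_equal(eff$classification, "nonsynonymous")
  expect_equal(eff$substitution, "I431L")

  # synonymous: GCT -> GCC
  pos_syn <- 100L + (10L - 1L) * 3L + 3L
  eff2 <- annotate_coding_effect(
    tibble::tibble(contig = "chr", pos = pos_syn, ref = "T", alt = "C"), g
  )
  expect_equal(eff2$classification, "synonymous")
  expect_true(is.na(eff2$substitution))

  # nonsense: internal TAT -> TAA (plant a TAT codon first)
  body2 <- body; body2[200] <- "TAT"
  g2 <- g
  g2$contigs[["chr"]] <- paste0(substr(g$contigs[["chr"]], 1, 100),
                                paste(body2, collapse = ""),
                                substr(g$contigs[["chr"]], 2501, nchar(g$contigs[["chr"]])))
  pos_non <- 100L + (200L - 1L) * 3L + 3L
  eff3 <- annotate_coding_effect(
    tibble::tibble(contig = "chr", pos = pos_non, ref = "T", alt = "A"), g2
  )
  expect_equal(eff3$classification, "nonsense")

  # start loss on the minus strand
  gm <- new_genome("m", c(chr = paste0("GG", as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds))), "GG")),
                   tibble::tibble(
                     contig = "chr", type = "CDS", start = 3L, end = 2L + 2400L,
                     strand = "-", feature_id = "gm", gene = "gm", product = "p", island = FALSE
                   ))
  # genomic base complementary to the A of ATG is the last base of the CDS interval
  pos_m <- 2L + 2400L
  eff4 <- annotate_coding_effect(
    tibble::tibble(contig = "chr", pos = pos_m, ref = "T", alt = "G"), gm
  )
  expect_equal(eff4$classification, "start_loss")

  # CDS length not divisible by 3 -> unclassified
  gbad <- new_genome("b", c(chr = paste0(cds, "GG")),
                     tibble::tibble(
                       contig = "chr", type = "CDS", start = 1L, end = 2401L,
                       strand = "+", feature_id = "gb", gene = "gb", product = "p", island = FALSE
                     ))
  eff5 <- annotate_coding_effect(
    tibble::tibble(contig = "chr", pos = 10L, ref = "T", alt = "C"), gbad
  )
  expect_equal(eff5$classification, "unclassified")
})

test_that("snp_scan ties calling, labelling, windows and contrast together", {
  sim <- carrier_pair(901)
  ref <- sim$genomes[[sim$carriers[1]]]
  qry <- sim$genomes[[sim$carriers[2]]]
  isl <- sim$truth$islands[1, ]
  scan <- snp_scan(ref, qry, island = isl)
  planted <- planted_mismatches(ref, qry)
  expect_equal(scan$snps$pos, planted)
  expect_equal(sum(scan$windows$n_snps), sum(scan$snps$region == "island"))
  expect_equal(nrow(scan$snps),
               sum(scan$snps$region %in% c("island", "backbone", "unaligned_adjacent")))
  expect_equal(scan$contrast$call, "recent_independent")

  # VCF round numbers: record count equals SNP count
  vcf <- withr::local_tempfile()
  write_snp_vcf(scan$snps, vcf)
  expect_equal(sum(!startsWith(readLines(vcf), "#")), nrow(scan$snps))
  bg <- withr::local_tempfile()
  write_bedgraph(scan$windows, bg)
  expect_equal(length(readLines(bg)) - 1, nrow(scan$windows))
})
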