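# Small-scale simulation fixtures shared across tests (kept minutes-scale).

tiny_clade <- function(seed, scenario = "recent_transfer", ...) {
  args <- utils::modifyList(
    list(
      scenario = scenario, n_carriers = 3, n_relatives = 1,
      genome_length = 30000, n_genes = 25, gene_length = 600,
      island_length = 8000, island_genes = 8, seed = seed
    ),
    list(...)
  )
  do.call(simulate_clade, args)
}

carrier_pair <- function(seed, scenario = "recent_transfer", ...) {
  tiny_clade(seed, scenario = scenario, n_carriers = 2, n_relatives = 0,
             genome_length = 30000, n_genes = 20, ...)
}

planted_mismatches <- function(a, b) {
  which(charToRaw(a$contigs[[1]]) != charToRaw(b$contigs[[1]]))
}
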