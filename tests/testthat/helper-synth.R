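# Small configurations for fast unit tests; the acceptance suite uses the
# package defaults.

small_config <- function(seed = 1, ...) {
  args <- list(
    n_genes = 120,
    n_case = list(a = c(20L, 20L), b = c(15L, 10L)),
    n_control = list(a = c(20L, 20L), b = c(15L, 10L)),
    module_sizes = c(30L, 30L),
    n_planted_hubs = 4,
    n_background_de = 10,
    n_assoc_genes = 60,
    n_decoys = 9,
    n_mirnas_a = 8, n_mirnas_b = 9, n_shared_mirnas = 3,
    targets_per_mirna = 8,
    immune_set_size = 10,
    n_pathway_decoys = 3,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}
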