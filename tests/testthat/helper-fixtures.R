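# Shared fixtures: a scaled-down configuration for fast unit tests and a
# hand-built sample sheet for one scenario.

small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 300, genes_per_phenotype = 5, seed = seed, ...)
}

# balanced one-scenario design: 3 blocks x G genotypes x 2 treatments
toy_design <- function(G = 4, B = 3) {
  d <- expand.grid(block = paste0("B", seq_len(B)),
                   genotype = paste0("GT", seq_len(G)),
                   treatment = c("control", "stressed"),
                   stringsAsFactors = FALSE)
  d$scenario <- "FDS"
  d$plant_id <- sprintf("S%02d", seq_len(nrow(d)))
  d
}

# deterministic tiny network for merge/annotation tests
toy_network <- function(edges, scenario = "FDS", phenotypes = c("OP", "E")) {
  scores <- matrix(0, length(unique(edges$gene)), length(phenotypes),
                   dimnames = list(unique(edges$gene), phenotypes))
  for (i in seq_len(nrow(edges))) {
    scores[edges$gene[i], edges$phenotype[i]] <- edges$score[i]
  }
  build_network(scores, threshold = 0.65, scenario = scenario)
}
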