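#!/usr/bin/env Rscript
# Stage 5 — sPLS regression and the gene-phenotype networks.
#
# Per scenario, fits a 3-component sparse PLS (regression mode, keepX =
# 50 genes per component) of the nine phenotypes on the normalized
# expression, exports the correlation-circle coordinates, accumulates
# pairwise association scores over the latent variates, thresholds them
# at |score| > 0.65 into a bipartite network, merges the two scenario
# networks and annotates genes with their ANOVA effect flags.

suppressMessages(library(droughtnet))

samples <- read_sample_sheet("results/dataset/samples.csv")
norm <- read_expression_tsv("results/03_expression_normalized.tsv")
phen <- utils::read.csv("results/dataset/phenotypes.csv")
traits <- c("ITW", "E", "OP", "RWC", "LMA", "CID", "PHe", "CoD", "TLA")

nets <- list(); fits <- list()
for (sc in c("FDS", "FIS")) {
  j <- which(samples$scenario == sc)
  Y <- as.matrix(phen[match(samples$plant_id[j], phen$plant_id), traits])
  rownames(Y) <- samples$plant_id[j]
  model <- fit_spls(t(norm[, j]), Y, n_components = 3, keepX = 50)
  coords <- export_coordinates(model)
  utils::write.table(coords$phenotypes,
                     sprintf("results/05_phenotype_coords_%s.tsv", sc),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(coords$samples,
                     sprintf("results/05_sample_coords_%s.tsv", sc),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sc_scores <- association_scores(model)
  nets[[sc]] <- build_network(sc_scores$scores, threshold = 0.65,
                              scenario = sc)
  fits[[sc]] <- model
  per_trait <- table(nets[[sc]]$edges$phenotype)
  message(sc, " network: ", nrow(nets[[sc]]$genes), " genes, ",
          nrow(nets[[sc]]$edges), " edges (",
          sum(nets[[sc]]$edges$sign == "pos"), " positive, ",
          sum(nets[[sc]]$edges$sign == "neg"), " negative)")
  print(per_trait)
}

# ANOVA annotations come from stage 4
anova_fds <- utils::read.delim("results/04_anova_FDS.tsv")
anova_fis <- utils::read.delim("results/04_anova_FIS.tsv")
reflag <- function(tab) {
  flags <- do.call(cbind, lapply(c("block", "genotype", "treatment", "gxt"),
                                 function(e) {
    s <- tab$significant[tab$effect == e]
    stats::setNames(s, tab$gene[tab$effect == e])
  }))
  colnames(flags) <- c("block", "genotype", "treatment", "gxt")
  list(flags = flags, classes = classify_effects(flags))
}
merged <- merge_networks(nets$FDS, nets$FIS)
merged <- annotate_nodes(merged, reflag(anova_fds), reflag(anova_fis))

memb <- table(merged$genes$membership)
message("merged network: ", nrow(merged$genes), " genes (",
        paste(sprintf("%s=%d", names(memb), memb), collapse = ", "),
        "), ", nrow(merged$edges), " edges")
export_network(merged, "results/05_network_merged")
message("wrote results/05_network_merged.{sif,graphml,_edges.tsv}")
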