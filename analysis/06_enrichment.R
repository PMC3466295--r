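#!/usr/bin/env Rscript
# Stage 6 — enrichment of the independent field gene list.
#
# Two analyses mirror the field-transfer result: (i) per-trait
# hypergeometric tests of whether the field drought-regulated genes are
# over-represented among network genes linked to that trait (both the
# point probability, the statistic the original analysis prints, and the
# upper-tail p-value are reported); (ii) a term-enrichment run of the
# field genes against the full gene universe with Benjamini-Yekutieli
# FDR, on a synthetic annotation built from the planted truth (one term
# per planted gene class plus random background terms).

suppressMessages(library(droughtnet))

field <- read_gene_list("results/dataset/field_genes.txt")
edges <- utils::read.delim("results/05_network_merged_edges.tsv",
                           colClasses = c(score = "numeric"))
genes <- sort(unique(edges$gene))
merged <- structure(
  list(edges = edges,
       genes = data.frame(gene = genes,
                          membership = rep("shared", length(genes)),
                          stringsAsFactors = FALSE),
       phenotypes = unique(edges$phenotype), threshold = 0.65),
  class = "assoc_network"
)

message(length(intersect(field, genes)), " of ", length(field),
        " field genes map into the ", length(genes), "-gene merged network")
tests <- do.call(rbind, lapply(sort(unique(edges$phenotype)), function(tr) {
  trait_link_enrichment(field, merged, tr)
}))
tests <- tests[order(tests$pmf), ]
print(tests, row.names = FALSE)
utils::write.csv(tests, "results/06_trait_link_tests.csv", row.names = FALSE)

sub <- field_subnetwork(field, merged)
export_network(sub, "results/06_field_subnetwork", formats = c("sif", "tsv"))
message("field subnetwork: ", nrow(sub$genes), " genes, ",
        nrow(sub$edges), " edges")

# synthetic term annotation from the planted truth: trait-linked genes
# share a term, each effect class shares a term, plus random background
truth <- jsonlite::read_json("results/dataset/truth.json",
                             simplifyVector = TRUE)
universe <- names(truth$effect_class)
ann <- rbind(
  data.frame(gene_id = unique(truth$associations$gene),
             term_id = "TERM:trait_linked", stringsAsFactors = FALSE),
  data.frame(gene_id = universe[unlist(truth$effect_class) != "none"],
             term_id = "TERM:stress_modulated", stringsAsFactors = FALSE),
  within(expand.grid(gene_id = universe[seq(1, length(universe), by = 7)],
                     stringsAsFactors = FALSE),
         term_id <- "TERM:background")
)
enr <- term_enrichment(intersect(field, universe), universe, ann)
print(enr, row.names = FALSE)
utils::write.csv(enr, "results/06_term_enrichment.csv", row.names = FALSE)
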