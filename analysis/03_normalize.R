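#!/usr/bin/env Rscript
# Stage 3 — post-summarization normalization.
#
# Per-gene block centering (subtract the block mean, restore the gene's
# global mean) followed by quantile normalization across all 96 chips,
# the same two steps the microarray analysis applies after RMA.

suppressMessages(library(droughtnet))

ds_dir <- "results/dataset"
expr <- read_expression_tsv(file.path(ds_dir, "expression.tsv"))
samples <- read_sample_sheet(file.path(ds_dir, "samples.csv"))

norm <- normalize_expression(expr, samples)
sorted <- apply(norm, 2, sort)
message("max deviation between sorted sample distributions: ",
        format(max(abs(sorted - sorted[, 1])), digits = 3))
message("gene global means preserved to: ",
        format(max(abs(rowMeans(norm) - rowMeans(quantile_normalize(
          block_center(expr, samples$block))))), digits = 3))
write_expression_tsv(norm, "results/03_expression_normalized.tsv")
message("wrote results/03_expression_normalized.tsv")
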