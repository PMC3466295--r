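#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic drought experiment.
#
# Emulates the study design: 8 genotypes x 2 treatments x 3 blocks per
# scenario (96 pots), daily pot weighing from irrigation stop, the two
# harvest rules (FDS: common day once half the treated plants pass
# FTSW < 0.35; FIS: per-plant crossing of FTSW < 0.1), a 2000-gene log2
# expression matrix with planted block/genotype/treatment/g*t effects,
# nine morpho-physiological phenotypes coupled to planted gene sets, and
# an independent "field" gene list enriched for trait-linked genes.

suppressMessages(library(droughtnet))

seed <- 1
outdir <- "results/dataset"
cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg)
files <- write_dataset(ds, outdir)

w <- ds$water
message("plants: ", nrow(ds$samples), "; genes: ", nrow(ds$expr))
message("FDS harvest day: ",
        unique(w$plants$harvest_day[w$plants$scenario == "FDS"]))
message("FIS harvest days: ",
        paste(range(w$plants$harvest_day[w$plants$scenario == "FIS"]),
              collapse = "-"))
message("planted effect classes:")
print(table(ds$truth$effect_class))
message("planted gene-phenotype associations: ",
        nrow(ds$truth$associations))
message("wrote: ", paste(basename(files), collapse = ", "))
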