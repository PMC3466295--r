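#!/usr/bin/env Rscript
# Stage 2 — water-status statistics from the pot-weight series.
#
# Recomputes, from the emitted files alone, each plant's FTSW trajectory
# and integrated transpired water (ITW = daily sum of 1 - FTSW up to the
# day before harvest), and checks them against the phenotype table. ITW
# separates the two scenarios: under FDS it measures stress intensity at
# the common harvest day, under FIS the time taken to reach harsh stress.

suppressMessages(library(droughtnet))

ds_dir <- "results/dataset"
pot <- utils::read.csv(file.path(ds_dir, "pot_weights.csv"))
samples <- read_sample_sheet(file.path(ds_dir, "samples.csv"))
phen <- utils::read.csv(file.path(ds_dir, "phenotypes.csv"))

# calibration constants of the default design
initial_weight <- 18000; final_weight <- 14000
ttsw <- compute_ttsw(initial_weight, final_weight)
message("TTSW: ", ttsw, " g")

harvest <- stats::aggregate(day ~ plant_id, pot, max)
plants <- merge(samples, harvest, by = "plant_id")
names(plants)[names(plants) == "day"] <- "harvest_day"
plants$is_control <- plants$treatment == "control"
plants <- plants[order(plants$plant_id), ]

water <- derive_water_phenotypes(pot, plants, final_weight, ttsw)
stopifnot(all(abs(water$itw - phen$ITW[match(water$plant_id,
                                             phen$plant_id)]) < 1e-6))
message("recomputed ITW matches the phenotype table for all ",
        nrow(water), " plants")

itw_by <- stats::aggregate(
  itw ~ scenario + treatment,
  merge(water, plants[, c("plant_id", "scenario", "treatment")]),
  mean)
print(itw_by)
dir.create("results", showWarnings = FALSE)
utils::write.csv(itw_by, "results/02_itw_by_group.csv", row.names = FALSE)
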