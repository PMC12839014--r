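#!/usr/bin/env Rscript
# Simulate the study inputs: a ChEMBL-like bioactivity table with mixed
# activity types, censored records, salt forms and duplicates; a drug-like
# decoy library; and a screening library with a small planted-active rate.
# Outputs land in results/data/.

library(chemsieve)

seed <- 1L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(n_compounds = 500L, seed = seed)
lib <- generate_library(cfg)
act <- assign_activities(lib, cfg)
write_activity_csv(act, file.path(out, "activity.csv"))

decoys <- generate_decoys(500L, seed = seed + 101L)
write_smi(decoys, file.path(out, "decoys.smi"))

screen_cfg <- synth_config(n_compounds = 10000L, seed = seed + 404L,
                           frac_pharmacophore = 0.05)
screen <- generate_library(screen_cfg)
write_smi(screen, file.path(out, "screening_library.smi"))

message(sprintf("activity table: %d records over %d compounds (%.0f%% IC50, %d censored)",
                nrow(act), cfg$n_compounds,
                100 * mean(act$activity_type == "IC50"),
                sum(act$relation == ">")))
message(sprintf("decoys: %d | screening library: %d (%.1f%% planted actives)",
                nrow(decoys), nrow(screen), 100 * mean(screen$has_pharmacophore)))
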