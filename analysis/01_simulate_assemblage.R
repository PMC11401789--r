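#!/usr/bin/env Rscript
# Builds the working synthetic assemblage used by the downstream analysis
# scripts: an Ulm-like sample (about 490 cheek teeth of two rhinocerotid
# species in a 2:1 ratio) with known ground truth, so every later step can
# be checked against what was put in.

suppressPackageStartupMessages(library(paleomolar))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 42L

dir.create("results", showWarnings = FALSE)
params <- ulm_params(seed = seed)
asm <- simulate_assemblage(params)
truth <- attr(asm, "truth")

write_assemblage(asm, "results/assemblage.csv")
jsonlite::write_json(
  list(seed = seed, n_individuals = params$n_individuals,
       n_teeth = nrow(asm),
       structure = as.list(setNames(truth$structure,
                                    c("juvenile", "subadult", "adult"))),
       species_masses = as.list(setNames(params$species$mass_kg,
                                         params$species$species))),
  "results/assemblage_truth.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("simulated %d teeth from %d individuals (seed %d)\n",
            nrow(asm), params$n_individuals, seed))
cat(sprintf("ground-truth age structure: %.1f%% juvenile, %.1f%% subadult, %.1f%% adult\n",
            truth$structure[1], truth$structure[2], truth$structure[3]))
cat("wrote results/assemblage.csv and results/assemblage_truth.json\n")
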