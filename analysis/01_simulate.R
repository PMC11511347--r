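#!/usr/bin/env Rscript
# Generate the synthetic SERS dataset of AMP/ADP/ATP mixtures under the
# default study conditions (7 mixing ratios x 20 replicates, 200-1700 cm^-1)
# and write it under results/data/.

suppressMessages(library(apsers))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1L]) else 1L

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- synthetic_config(seed = seed)
set <- generate_dataset(cfg)
print(set)
paths <- write_spectra(set, "results/data/raw")
cat("grid:", length(set$shifts), "points,",
    cfg$grid_lo, "-", cfg$grid_hi, "cm^-1 at", cfg$grid_step, "cm^-1\n")
cat("wrote", paths["csv"], "and", paths["json"], "\n")
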