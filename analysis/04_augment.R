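#!/usr/bin/env Rscript
# Build the augmented training pool for one training half: 40 noise-model
# copies per training spectrum plus 100 SMOTE interpolants per group,
# i.e. 70 + 2800 + 700 = 3570 labelled points in feature-selected space.

suppressMessages(library(apsers))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1L]) else 1L

pp <- read_spectra("results/data/preprocessed")
train <- split_train_test(pp, seed = seed)$train
mask <- select_features(train, seed = seed)
train <- apply_mask(train, mask)

pool <- build_training_pool(train, augmentation_config(seed = seed))
print(pool)
write_spectra(pool, "results/data/training_pool")
cat("wrote results/data/training_pool.{csv,json}\n")
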