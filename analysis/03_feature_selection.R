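#!/usr/bin/env Rscript
# Fit the k-means feature mask on one training half: cluster the Raman
# shifts by their intensity profiles, choose k by the elbow method, and
# drop the least class-informative (noise) cluster. Writes the mask and
# the per-cluster summary.

suppressMessages(library(apsers))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1L]) else 1L

pp <- read_spectra("results/data/preprocessed")
train <- split_train_test(pp, seed = seed)$train
mask <- select_features(train, k_max = 10L, n_drop = 1L, seed = seed)

cat("elbow chose k =", mask$k, "clusters; wcss curve:\n")
print(round(mask$wcss, 1))
scores <- attr(identify_noise_clusters(mask$assignment, train,
                                       n_drop = length(mask$dropped_clusters)),
               "scores")
for (c in seq_len(mask$k)) {
  members <- train$shifts[mask$assignment$labels == c]
  cat(sprintf("cluster %d: %d shifts, score %.4f, range %.0f-%.0f cm^-1%s\n",
              c, length(members), scores[c], min(members), max(members),
              if (c %in% mask$dropped_clusters) "  [dropped: noise]" else ""))
}
cat("retained", length(mask$selected), "of", length(mask$grid), "shifts\n")

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(k = mask$k, labels = mask$assignment$labels,
       dropped_clusters = mask$dropped_clusters,
       selected_shifts = mask$selected_shifts, seed = seed),
  "results/feature_mask.json", auto_unbox = TRUE, digits = NA
)
cat("wrote results/feature_mask.json\n")
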