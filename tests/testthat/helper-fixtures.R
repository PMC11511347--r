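# Small configurations and constructed sets shared across test files.

# fast generator config: coarse grid, few replicates
tiny_config <- function(..., replicates_per_ratio = 4, grid_step = 10, seed = 42L) {
  synthetic_config(replicates_per_ratio = replicates_per_ratio,
                   grid_step = grid_step, seed = seed, ...)
}

# noiseless config whose spectra equal their clean renders exactly
clean_config <- function(replicates_per_ratio = 2, grid_step = 10, seed = 7L) {
  synthetic_config(
    replicates_per_ratio = replicates_per_ratio, grid_step = grid_step,
    noise_sd = 0, enhancement_sd = 0,
    baseline_coeff_ranges = matrix(0, 6, 2), seed = seed
  )
}

# hand-built ap_spectra from an intensity matrix and group ids
make_set <- function(intensities, group_id, shifts = seq_len(nrow(intensities))) {
  ratios <- ap_mixing_ratios()
  labels <- do.call(rbind, lapply(seq_along(group_id), function(i) {
    apsers:::ap_labels(sprintf("t%d", i), group_id[i], ratios[group_id[i], ])
  }))
  ap_spectra(shifts, intensities, labels)
}

# shift-profile matrix with well-separated row groups (for elbow tests):
# `centers` is a list of prototype rows; each is replicated `per` times
# with N(0, jitter) perturbation
grouped_rows <- function(centers, per = 10, jitter = 0.05, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(centers, function(mu) {
    t(replicate(per, mu + rnorm(length(mu), 0, jitter)))
  }))
}

# brute-force minimum-WCSS partition of the rows of x into k non-empty
# clusters, by exhaustive enumeration of assignments
brute_force_wcss <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      w <- sum(vapply(seq_len(k), function(c) {
        rows <- x[assign == c, , drop = FALSE]
        if (nrow(rows) == 0L) return(0)
        sum(sweep(rows, 2L, colMeans(rows))^2)
      }, 0))
      if (w < best) best <- w
    }
    i <- n
    while (i >= 1L && assign[i] == k) { assign[i] <- 1L; i <- i - 1L }
    if (i == 0L) break
    assign[i] <- assign[i] + 1L
  }
  best
}
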