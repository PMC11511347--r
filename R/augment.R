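#' Augmentation configuration
#'
#' Controls how much synthetic training data the two augmenters emit.
#' Defaults reproduce the study counts: 40 noise copies per training
#' spectrum (70 originals -> 2800 noise synthetics) and 100 SMOTE points
#' per group (7 groups -> 700), for a 3570-point training pool.
#'
#' @param noise_factor Noise-injected copies per training spectrum
#'   (default 40).
#' @param smote_per_class SMOTE synthetics per mixing-ratio group
#'   (default 100).
#' @param smote_k Nearest neighbors considered per SMOTE draw (default 5).
#' @param seed RNG seed.
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(noise_factor = 40L, smote_per_class = 100L,
                                smote_k = 5L, seed = 1L) {
  stopifnot(noise_factor >= 0, smote_per_class >= 0, smote_k >= 1)
  structure(
    list(noise_factor = as.integer(noise_factor),
         smote_per_class = as.integer(smote_per_class),
         smote_k = as.integer(smote_k), seed = as.integer(seed)),
    class = "augmentation_config"
  )
}

#' Per-group, per-shift noise standard deviations
#'
#' Estimates s[i, j], the sample standard deviation of intensity at Raman
#' shift j over the training spectra of group i — the noise scale used by
#' group-conditional noise injection.
#'
#' @param train A training [ap_spectra()]; every group must have at least
#'   2 spectra.
#' @return A list of class `group_noise_model`: `s` (groups x shifts
#'   matrix, rownames the group ids) and `shifts`.
#' @export
estimate_group_noise <- function(train) {
  stopifnot(inherits(train, "ap_spectra"))
  groups <- sort(unique(train$labels$group_id))
  counts <- table(factor(train$labels$group_id, levels = groups))
  if (any(counts < 2L)) {
    stop("group(s) with fewer than 2 training spectra: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  s <- t(vapply(groups, function(g) {
    apply(train$intensities[, train$labels$group_id == g, drop = FALSE], 1L,
          stats::sd)
  }, numeric(length(train$shifts))))
  rownames(s) <- as.character(groups)
  structure(list(s = s, shifts = train$shifts), class = "group_noise_model")
}

#' Group-conditional Gaussian noise injection
#'
#' For each training spectrum of group i, emits `noise_factor` synthetic
#' copies original + n, with n[j] = s[i, j] * N(0, 1) drawn freshly per
#' copy and per shift. Synthetic points inherit the source's labels.
#'
#' @param train A training [ap_spectra()].
#' @param model A [estimate_group_noise()] result covering every group in
#'   `train`.
#' @param config An [augmentation_config()] (`noise_factor`, `seed`).
#' @return An `ap_spectra` of `n_spectra(train) * noise_factor` synthetic
#'   spectra, origin `"noise"`, ids `<source>_n<copy>`.
#' @export
augment_noise <- function(train, model, config = augmentation_config()) {
  stopifnot(inherits(train, "ap_spectra"), inherits(model, "group_noise_model"))
  missing_g <- setdiff(unique(train$labels$group_id),
                       as.integer(rownames(model$s)))
  if (length(missing_g)) {
    stop("noise model lacks group(s): ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  }
  set.seed(config$seed)
  p <- length(train$shifts)
  total <- n_spectra(train) * config$noise_factor
  out <- matrix(0, nrow = p, ncol = total)
  labs <- vector("list", total)
  ids <- character(total)
  col <- 0L
  for (j in seq_len(n_spectra(train))) {
    src <- train$intensities[, j]
    lab <- train$labels[j, ]
    s <- model$s[as.character(lab$group_id), ]
    for (c in seq_len(config$noise_factor)) {
      col <- col + 1L
      out[, col] <- src + s * stats::rnorm(p)
      ids[col] <- sprintf("%s_n%d", lab$id, c)
      labs[[col]] <- ap_labels(ids[col], lab$group_id,
                               c(lab$ratio_amp, lab$ratio_adp, lab$ratio_atp),
                               origin = "noise", source_id = lab$id)
    }
  }
  if (total == 0L) {
    return(subset_spectra(train, integer(0)))
  }
  ap_spectra(train$shifts, out, do.call(rbind, labs))
}

#' SMOTE oversampling within mixing-ratio groups
#'
#' Native SMOTE: per group, repeat `smote_per_class` times — pick a random
#' member x, pick one of its `smote_k` nearest same-group neighbors z
#' (Euclidean distance in the current feature space, distance ties broken
#' by lower spectrum index), and emit x + u (z - x) with u ~ Uniform(0,1).
#' Synthetic points take the group's labels and always lie on the segment
#' [x, z]. Implemented natively so the per-class counts are forced exactly
#' even though all groups are balanced.
#'
#' @param train A training [ap_spectra()]; every group needs at least
#'   `smote_k + 1` members.
#' @param config An [augmentation_config()] (`smote_per_class`, `smote_k`,
#'   `seed`).
#' @return An `ap_spectra` of `smote_per_class` synthetics per group,
#'   origin `"smote"`, ids `g<group>_s<copy>`, `source_id` `"x|z"`.
#' @export
smote_oversample <- function(train, config = augmentation_config()) {
  stopifnot(inherits(train, "ap_spectra"))
  set.seed(config$seed + 1L)
  groups <- sort(unique(train$labels$group_id))
  pieces <- list()
  for (g in groups) {
    idx <- which(train$labels$group_id == g)
    ng <- length(idx)
    if (ng < config$smote_k + 1L) {
      stop(sprintf("group %d has %d member(s); smote_k = %d needs at least %d",
                   g, ng, config$smote_k, config$smote_k + 1L), call. = FALSE)
    }
    if (config$smote_per_class == 0L) next
    x <- train$intensities[, idx, drop = FALSE]
    d <- as.matrix(stats::dist(t(x)))
    ratio <- unlist(train$labels[idx[1L],
                                 c("ratio_amp", "ratio_adp", "ratio_atp")])
    cols <- matrix(0, nrow = nrow(x), ncol = config$smote_per_class)
    labs <- vector("list", config$smote_per_class)
    for (r in seq_len(config$smote_per_class)) {
      i <- sample.int(ng, 1L)
      nbr <- setdiff(order(d[i, ], seq_len(ng)), i)[seq_len(config$smote_k)]
      z <- nbr[sample.int(config$smote_k, 1L)]
      u <- stats::runif(1L)
      cols[, r] <- x[, i] + u * (x[, z] - x[, i])
      id <- sprintf("g%d_s%d", g, r)
      labs[[r]] <- ap_labels(id, g, ratio, origin = "smote",
                             source_id = paste(train$labels$id[idx[c(i, z)]],
                                               collapse = "|"))
    }
    lab_df <- do.call(rbind, labs)
    colnames(cols) <- lab_df$id
    pieces[[as.character(g)]] <- ap_spectra(train$shifts, cols, lab_df)
  }
  if (length(pieces) == 0L) return(subset_spectra(train, integer(0)))
  do.call(bind_spectra, unname(pieces))
}

#' Assemble the augmented training pool
#'
#' Originals + noise synthetics + SMOTE synthetics, in that order. Both
#' augmenters run on the original training spectra (not on each other's
#' output), keeping the two augmentations independent. With the default
#' configuration and 70 training spectra the pool holds
#' 70 + 2800 + 700 = 3570 labelled points. Test data must never be passed
#' here.
#'
#' @param train A preprocessed, feature-selected training [ap_spectra()].
#' @param config An [augmentation_config()].
#' @return The pooled `ap_spectra`.
#' @export
build_training_pool <- function(train, config = augmentation_config()) {
  model <- estimate_group_noise(train)
  noisy <- augment_noise(train, model, config)
  smoted <- smote_oversample(train, config)
  bind_spectra(train, noisy, smoted)
}
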