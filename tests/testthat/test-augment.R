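test_that("group noise model is the per-group, per-shift sample sd", {
  # a group of identical spectra has zero sd everywhere
  x <- cbind(rep(2, 5), rep(2, 5), rep(3, 5), rep(7, 5))
  set <- make_set(x, c(1L, 1L, 2L, 2L))
  model <- estimate_group_noise(set)
  expect_equal(unname(model$s["1", ]), rep(0, 5))
  # two-point group: sd = |a - b| / sqrt(2)
  expect_equal(unname(model$s["2", ]), rep(4 / sqrt(2), 5))

  solo <- make_set(cbind(rep(1, 5), rep(2, 5), rep(2.5, 5)), c(1L, 2L, 2L))
  expect_error(estimate_group_noise(solo), "fewer than 2")
})

test_that("synthetic-data noise is signal-dependent at band shifts", {
  # multiplicative enhancement variability scales with the signal, so on
  # raw spectra (before standardization cancels the per-spectrum scale)
  # the group sd is larger on bands than in band-free regions
  raw <- generate_dataset(synthetic_config(
    enhancement_sd = 0.3, noise_sd = 0.005,
    baseline_coeff_ranges = matrix(0, 6, 2), seed = 6L
  ))
  train <- split_train_test(raw, seed = 6L)$train
  model <- estimate_group_noise(train)
  expect_true(all(model$s > 0))
  band_idx <- which(abs(raw$shifts - 730) <= 10)
  flat_idx <- which(raw$shifts >= 250 & raw$shifts <= 550)
  expect_gt(mean(model$s[, band_idx]), mean(model$s[, flat_idx]))

  # on preprocessed spectra the model stays strictly positive everywhere
  pp_model <- estimate_group_noise(
    split_train_test(preprocess_set(raw), seed = 6L)$train
  )
  expect_true(all(pp_model$s > 0))
})

test_that("noise injection emits the configured number of labelled copies", {
  set.seed(1)
  x <- matrix(rnorm(6 * 14), 6, 14)
  set <- make_set(x, rep(1:7, each = 2L))
  model <- estimate_group_noise(set)
  aug <- augment_noise(set, model, augmentation_config(noise_factor = 40L))
  expect_equal(n_spectra(aug), 14L * 40L)
  expect_true(all(aug$labels$origin == "noise"))
  # label conservation: each copy matches its source's group and ratios
  src <- match(aug$labels$source_id, set$labels$id)
  expect_false(anyNA(src))
  expect_equal(aug$labels$group_id, set$labels$group_id[src])
  expect_equal(aug$labels$ratio_atp, set$labels$ratio_atp[src])

  # degenerate model: all copies identical to their source
  zero <- model
  zero$s[] <- 0
  still <- augment_noise(set, zero, augmentation_config(noise_factor = 3L))
  for (j in seq_len(n_spectra(still))) {
    s <- match(still$labels$source_id[j], set$labels$id)
    expect_equal(still$intensities[, j], set$intensities[, s],
                 ignore_attr = TRUE)
  }

  dropped <- subset_spectra(set, 3:14)  # group 1 absent from train
  expect_error(augment_noise(dropped, estimate_group_noise(dropped),
                             augmentation_config()), NA)
})

test_that("noise copies are centred on the source with the model's sd", {
  # Monte-Carlo check of the group-noise model: mean -> source,
  # per-shift sd -> s within stated tolerances
  x <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  set <- make_set(x, c(1L, 1L))
  model <- estimate_group_noise(set)
  s_true <- unname(model$s["1", ])
  expect_equal(s_true, rep(1 / sqrt(2), 4))

  one <- subset_spectra(set, 1L)
  copies <- augment_noise(one, model,
                          augmentation_config(noise_factor = 1e4L, seed = 2L))
  emp_mean <- rowMeans(copies$intensities)
  emp_sd <- apply(copies$intensities, 1L, sd)
  expect_true(all(abs(emp_mean - x[, 1L]) <= 4 * s_true / 100))
  expect_true(all(abs(emp_sd - s_true) / s_true < 0.05))
})

test_that("SMOTE emits per-group counts on segments between neighbors", {
  set.seed(3)
  x <- matrix(rnorm(5 * 42), 5, 42)
  set <- make_set(x, rep(1:7, each = 6L))
  aug <- smote_oversample(set, augmentation_config(smote_per_class = 100L))
  expect_equal(n_spectra(aug), 700L)
  expect_equal(unname(table(aug$labels$group_id)), rep(100L, 7L),
               ignore_attr = TRUE)
  expect_true(all(aug$labels$origin == "smote"))

  # convexity: every synthetic point lies coordinate-wise between its parents
  parents <- strsplit(aug$labels$source_id, "|", fixed = TRUE)
  for (j in seq_len(50L)) {
    pid <- match(parents[[j]], set$labels$id)
    lo <- pmin(set$intensities[, pid[1L]], set$intensities[, pid[2L]])
    hi <- pmax(set$intensities[, pid[1L]], set$intensities[, pid[2L]])
    expect_true(all(aug$intensities[, j] >= lo - 1e-12 &
                      aug$intensities[, j] <= hi + 1e-12))
  }

  # a group collapsed to one point reproduces that point
  collapsed <- set
  for (g in 1:7) {
    idx <- which(collapsed$labels$group_id == g)
    collapsed$intensities[, idx] <- collapsed$intensities[, idx[1L]]
  }
  rep_pts <- smote_oversample(collapsed,
                              augmentation_config(smote_per_class = 5L))
  for (j in seq_len(n_spectra(rep_pts))) {
    g <- rep_pts$labels$group_id[j]
    proto <- collapsed$intensities[, which(collapsed$labels$group_id == g)[1L]]
    expect_equal(rep_pts$intensities[, j], proto, ignore_attr = TRUE)
  }

  small <- make_set(matrix(rnorm(5 * 14), 5, 14), rep(1:7, each = 2L))
  expect_error(smote_oversample(small, augmentation_config(smote_k = 5L)),
               "group 1")
})

test_that("the training pool concatenates originals and both augmentations", {
  set.seed(4)
  x <- matrix(rnorm(6 * 70), 6, 70)
  set <- make_set(x, rep(1:7, each = 10L))
  pool <- build_training_pool(set, augmentation_config(seed = 11L))
  expect_equal(n_spectra(pool), 70L + 2800L + 700L)
  expect_equal(unname(table(pool$labels$origin)[c("measured", "noise", "smote")]),
               c(70L, 2800L, 700L), ignore_attr = TRUE)

  # FSD degenerate case: no augmentation at all
  bare <- build_training_pool(set, augmentation_config(noise_factor = 0L,
                                                       smote_per_class = 0L))
  expect_equal(bare$intensities, set$intensities)

  # determinism: same seed, same pool
  again <- build_training_pool(set, augmentation_config(seed = 11L))
  expect_identical(pool, again)
})
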