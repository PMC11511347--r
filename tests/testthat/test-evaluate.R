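# easy, fast dataset: clean spectra, well separated, coarse grid
easy_dataset <- function(replicates = 4L, seed = 5L) {
  preprocess_set(generate_dataset(synthetic_config(
    replicates_per_ratio = replicates, grid_step = 10,
    noise_sd = 0.002, enhancement_sd = 0.05,
    adenine_offsets = c(AMP = -5, ADP = 0, ATP = 5), seed = seed
  )))
}

small_aug <- function(seed = 1L) {
  augmentation_config(noise_factor = 3L, smote_per_class = 5L, smote_k = 1L,
                      seed = seed)
}

test_that("the stratified half split puts half of each group on each side", {
  set <- generate_dataset(synthetic_config(grid_step = 10, seed = 2L))
  halves <- split_train_test(set, seed = 4L)
  expect_equal(n_spectra(halves$train), 70L)
  expect_equal(n_spectra(halves$test), 70L)
  expect_equal(unname(table(halves$train$labels$group_id)), rep(10L, 7L),
               ignore_attr = TRUE)
  expect_equal(unname(table(halves$test$labels$group_id)), rep(10L, 7L),
               ignore_attr = TRUE)
  # partition: no overlap, full coverage
  expect_length(intersect(halves$train$labels$id, halves$test$labels$id), 0L)
  expect_setequal(c(halves$train$labels$id, halves$test$labels$id),
                  set$labels$id)

  tiny <- generate_dataset(tiny_config(replicates_per_ratio = 2))
  h <- split_train_test(tiny, seed = 1L)
  expect_equal(n_spectra(h$train), 7L)

  again <- split_train_test(set, seed = 4L)
  expect_identical(again$train$labels$id, halves$train$labels$id)

  odd <- subset_spectra(set, -1L)
  expect_error(split_train_test(odd, seed = 1L), "odd")
})

test_that("run_condition pools one prediction per spectrum over the swap", {
  data <- easy_dataset()
  res <- run_condition(data, "RD", model_spec("kNN", list(k = 1L)), seed = 2L)
  expect_equal(nrow(res$predictions), n_spectra(data))
  expect_setequal(res$predictions$id, data$labels$id)
  expect_equal(sum(res$confusion), n_spectra(data))
  # RD fits no mask
  expect_true(all(vapply(res$masks, is.null, NA)))
  # clean well-separated groups are classified perfectly
  expect_equal(res$accuracy, 1)
  expect_equal(res$per_analyte, 1)
})

test_that("FSD and DAD fit their stages per fold on the training half only", {
  data <- easy_dataset()
  res <- run_condition(data, "DAD", model_spec("kNN", list(k = 1L)),
                       seed = 3L, aug = small_aug())
  expect_length(res$masks, 2L)
  expect_true(all(vapply(res$masks, inherits, NA, "feature_mask")))
  expect_equal(nrow(res$predictions), n_spectra(data))

  # leakage guard: perturbing test-half intensities leaves each fold's
  # fitted mask identical
  halves <- split_train_test(data, seed = 3L)
  perturbed <- data
  test_cols <- match(halves$test$labels$id, data$labels$id)
  perturbed$intensities[, test_cols] <-
    perturbed$intensities[, test_cols] + rnorm(length(test_cols) * nrow(perturbed$intensities))
  # re-standardize so the set is valid preprocessed input
  perturbed$intensities[, test_cols] <- apply(
    perturbed$intensities[, test_cols, drop = FALSE], 2L,
    function(v) (v - mean(v)) / sd(v)
  )
  res2 <- run_condition(perturbed, "DAD", model_spec("kNN", list(k = 1L)),
                        seed = 3L, aug = small_aug())
  # fold 1 fits on the training half, so its mask cannot see the
  # perturbation; fold 2 trains on the swapped half by design
  expect_identical(res$masks[[1L]], res2$masks[[1L]])
})

test_that("run_benchmark fills the condition x family table and isolates failures", {
  data <- easy_dataset()
  specs <- list(kNN = model_spec("kNN", list(k = 1L)),
                DT = model_spec("DT", list(maxdepth = 8L)))
  rep <- run_benchmark(data, specs, seed = 6L, aug = small_aug())
  expect_equal(nrow(rep$table), 6L)  # 3 conditions x 2 families
  expect_true(all(rep$table$accuracy >= 0 & rep$table$accuracy <= 1))
  expect_true(all(rep$table$n == n_spectra(data)))
  expect_length(rep$errors, 0L)

  one <- run_benchmark(data, specs["kNN"], conditions = "RD", seed = 6L)
  expect_equal(nrow(one$table), 1L)

  # a family whose spec is broken fails alone
  bad <- c(specs, list(SVM = model_spec("SVM", list(cost = -5))))
  rep2 <- run_benchmark(data, bad, conditions = "RD", seed = 6L,
                        aug = small_aug())
  expect_true("RD.SVM" %in% names(rep2$errors))
  expect_equal(nrow(rep2$table), 2L)
})

test_that("benchmark reports regenerate identically from config and seed", {
  data <- easy_dataset(seed = 9L)
  specs <- list(kNN = model_spec("kNN", list(k = 3L)))
  r1 <- run_benchmark(data, specs, seed = 21L, aug = small_aug())
  r2 <- run_benchmark(data, specs, seed = 21L, aug = small_aug())
  expect_identical(r1, r2)
})

test_that("summarize_errors reproduces per-group rates from the confusions", {
  data <- easy_dataset()
  specs <- list(kNN = model_spec("kNN", list(k = 1L)))
  rep <- run_benchmark(data, specs, conditions = c("RD", "FSD"), seed = 2L)
  errs <- summarize_errors(rep)
  expect_equal(errs$errors$error_rate, rep(0, nrow(errs$errors)))

  # arithmetic: error = 1 - diagonal / row sum on a forged report
  forged <- rep
  cm <- forged$confusions[["RD.kNN"]]
  cm["1", "1"] <- cm["1", "1"] - 2L
  cm["1", "7"] <- cm["1", "7"] + 2L
  forged$confusions[["RD.kNN"]] <- cm
  errs2 <- summarize_errors(forged)
  row1 <- errs2$errors[errs2$errors$condition == "RD" & errs2$errors$group == 1L, ]
  expect_equal(row1$error_rate, 2 / sum(cm["1", ]))
  worst <- errs2$worst[errs2$worst$condition == "RD", ]
  expect_equal(worst$group, 1L)
})
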