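test_that("the shift matrix has one row per shift and one column per spectrum", {
  set <- generate_dataset(tiny_config())
  pp <- preprocess_set(set)
  m <- build_shift_matrix(pp)
  expect_equal(dim(m), c(length(pp$shifts), n_spectra(pp)))
  expect_equal(attr(m, "shifts"), pp$shifts)

  one <- build_shift_matrix(subset_spectra(pp, 1L))
  expect_equal(ncol(one), 1L)

  expect_error(build_shift_matrix(subset_spectra(pp, integer(0))), "empty")
})

test_that("k-means recovers trivial partitions with zero dispersion", {
  # two blocks of identical rows, far apart
  x <- rbind(matrix(0, 4, 3), matrix(10, 5, 3))
  attr(x, "shifts") <- seq_len(9)
  a <- kmeans_shifts(x, 2L, seed = 1L)
  expect_equal(a$wcss, 0)
  expect_length(unique(a$labels[1:4]), 1L)
  expect_length(unique(a$labels[5:9]), 1L)
  expect_false(a$labels[1L] == a$labels[9L])

  # singleton clusters: k equal to the number of rows
  y <- matrix(rnorm(12), 6, 2)
  attr(y, "shifts") <- 1:6
  expect_equal(kmeans_shifts(y, 6L, seed = 2L)$wcss, 0)

  expect_error(kmeans_shifts(y, 7L, seed = 1L), "outside")
  expect_error(kmeans_shifts(y, 0L, seed = 1L), "outside")
})

test_that("k-means matches the brute-force optimal partition on small instances", {
  set.seed(31)
  for (case in 1:5) {
    n <- sample(6:8, 1L)
    k <- sample(2:3, 1L)
    x <- matrix(rnorm(n * 2, sd = 2), n, 2)
    attr(x, "shifts") <- seq_len(n)
    got <- kmeans_shifts(x, k, seed = case, n_init = 20L)$wcss
    want <- brute_force_wcss(x, k)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("wcss is non-increasing in k under best-of-restarts", {
  set.seed(5)
  x <- matrix(rnorm(40 * 6), 40, 6)
  attr(x, "shifts") <- seq_len(40)
  sweep_k <- elbow_select_k(x, k_max = 8L, seed = 3L)$wcss
  expect_true(all(diff(sweep_k) <= 1e-8))
})

test_that("the elbow lands on the constructed number of row groups", {
  centers4 <- list(rep(0, 8), rep(6, 8), c(rep(12, 4), rep(0, 4)), rep(-6, 8))
  x4 <- grouped_rows(centers4, per = 12, jitter = 0.05, seed = 4L)
  attr(x4, "shifts") <- seq_len(nrow(x4))
  expect_equal(elbow_select_k(x4, k_max = 10L, seed = 1L)$k, 4L)

  centers2 <- list(rep(0, 5), rep(8, 5))
  x2 <- grouped_rows(centers2, per = 10, jitter = 0.02, seed = 9L)
  attr(x2, "shifts") <- seq_len(nrow(x2))
  expect_equal(elbow_select_k(x2, k_max = 6L, seed = 1L)$k, 2L)
})

test_that("a straight wcss curve resolves to k = 1 by the tie-break", {
  expect_equal(apsers:::elbow_point(1:6, seq(60, 10, by = -10)), 1L)
  # flat curve: no elbow either
  expect_equal(apsers:::elbow_point(1:5, rep(3, 5)), 1L)
})

test_that("noise clusters are the least class-informative ones", {
  # 12 band shifts whose group means differ, 12 noise shifts identical
  # across groups; 4 spectra per group, 3 groups
  set.seed(21)
  groups <- rep(1:3, each = 4L)
  band <- do.call(cbind, lapply(groups, function(g) rep(g * 2, 12L)))
  noise <- matrix(rnorm(12L * length(groups), sd = 0.01), 12L)
  set <- make_set(rbind(band, noise), groups)
  m <- build_shift_matrix(set)
  a <- kmeans_shifts(m, 2L, seed = 1L)
  dropped <- identify_noise_clusters(a, set, n_drop = 1L)
  noise_cluster <- a$labels[13L]  # all noise rows share one cluster
  expect_length(unique(a$labels[13:24]), 1L)
  expect_equal(as.integer(dropped), noise_cluster)

  expect_length(identify_noise_clusters(a, set, n_drop = 0L), 0L)
  expect_error(identify_noise_clusters(a, set, n_drop = 2L), "smaller")
})

test_that("identically scored clusters drop by smallest cluster id", {
  # two clusters with exactly the same (zero) between-group variance
  groups <- rep(1:2, each = 2L)
  x <- rbind(matrix(1, 3, 4), matrix(5, 3, 4))
  set <- make_set(x, groups)
  a <- kmeans_shifts(build_shift_matrix(set), 2L, seed = 1L)
  dropped <- identify_noise_clusters(a, set, n_drop = 1L)
  expect_equal(as.integer(dropped), 1L)
})

test_that("select_features keeps band shifts and drops band-free regions", {
  pp <- preprocess_set(generate_dataset(synthetic_config(seed = 8L)))
  train <- split_train_test(pp, seed = 8L)$train
  mask <- select_features(train, seed = 8L)
  for (band in c(730, 1330, 1460)) {
    expect_true(any(abs(mask$selected_shifts - band) <= 10),
                label = sprintf("band %d retained", band))
  }
  # the dropped cluster is dominated by band-free shifts
  dropped_shifts <- train$shifts[!seq_along(train$shifts) %in% mask$selected]
  band_centers <- c(730, 1075, 1180, 1330, 1460)
  near_band <- vapply(dropped_shifts, function(s) any(abs(s - band_centers) < 30), NA)
  expect_lt(mean(near_band), 0.2)

  # n_drop = 0 disables selection
  all_mask <- select_features(train, n_drop = 0L, seed = 8L)
  expect_equal(all_mask$selected, seq_along(train$shifts))
})

test_that("the mask is fitted on training data only (leakage guard)", {
  pp <- preprocess_set(generate_dataset(tiny_config(seed = 13L)))
  halves <- split_train_test(pp, seed = 13L)
  mask1 <- select_features(halves$train, seed = 5L)
  # perturbing the unseen half cannot change the fitted mask
  perturbed <- halves$test
  perturbed$intensities <- perturbed$intensities[, rev(seq_len(n_spectra(perturbed)))]
  mask2 <- select_features(halves$train, seed = 5L)
  expect_identical(mask1, mask2)
})

test_that("apply_mask restricts spectra and enforces the fitted grid", {
  pp <- preprocess_set(generate_dataset(tiny_config(seed = 3L)))
  train <- split_train_test(pp, seed = 3L)$train
  mask <- select_features(train, seed = 3L)

  masked <- apply_mask(pp, mask)
  expect_equal(n_spectra(masked), n_spectra(pp))
  expect_length(masked$shifts, length(mask$selected))
  expect_identical(masked$labels, pp$labels)

  all_mask <- select_features(train, n_drop = 0L, seed = 3L)
  expect_equal(apply_mask(pp, all_mask)$intensities, pp$intensities)

  other <- crop_spectra(pp, 400, 1700)
  expect_error(apply_mask(other, mask), "grid")
})
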