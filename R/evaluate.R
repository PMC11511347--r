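#' Stratified half split
#'
#' Randomly assigns exactly half of each mixing-ratio group to the
#' training side and half to the test side (the study design: 140 spectra
#' -> 70 + 70, 10 per group on each side). Reproducible under a fixed
#' seed.
#'
#' @param set An [ap_spectra()] with an even number of spectra per group.
#' @param seed RNG seed.
#' @return A list with `ap_spectra` elements `train` and `test`.
#' @export
split_train_test <- function(set, seed = 1L) {
  stopifnot(inherits(set, "ap_spectra"))
  set.seed(seed)
  groups <- sort(unique(set$labels$group_id))
  train_idx <- integer(0)
  for (g in groups) {
    idx <- which(set$labels$group_id == g)
    if (length(idx) %% 2L != 0L) {
      stop(sprintf("group %d has odd size %d; cannot half-split", g, length(idx)),
           call. = FALSE)
    }
    train_idx <- c(train_idx, sample(idx, length(idx) / 2L))
  }
  train_idx <- sort(train_idx)
  list(train = subset_spectra(set, train_idx),
       test = subset_spectra(set, setdiff(seq_len(n_spectra(set)), train_idx)))
}

#' Feature-selection settings used by the benchmark
#'
#' @param k_max Elbow sweep upper bound.
#' @param n_drop Noise clusters removed.
#' @param n_init k-means restarts.
#' @return A plain list.
#' @export
fs_config <- function(k_max = 10L, n_drop = 1L, n_init = 10L) {
  list(k_max = as.integer(k_max), n_drop = as.integer(n_drop),
       n_init = as.integer(n_init))
}

# Prepare one swap fold under one condition: returns the training pool,
# the matching test set and the fitted mask (NULL under RD). Everything
# fitted here sees only the training half.
prepare_fold <- function(train, test, condition, fs, aug, seed) {
  mask <- NULL
  if (condition %in% c("FSD", "DAD")) {
    mask <- select_features(train, k_max = fs$k_max, n_drop = fs$n_drop,
                            seed = seed, n_init = fs$n_init)
    train <- apply_mask(train, mask)
    test <- apply_mask(test, mask)
  }
  pool <- train
  if (condition == "DAD") {
    aug$seed <- seed
    pool <- build_training_pool(train, aug)
  }
  list(pool = pool, test = test, mask = mask)
}

#' Run one (condition, family) cell with the train/test swap
#'
#' The two-fold swap protocol: the set is half-split once; each half
#' serves once as training and once as test. Per fold, the feature mask
#' (FSD/DAD) and the noise model + augmentation (DAD) are fitted on the
#' training half only, the model is trained on the resulting pool, and the
#' held-out half is predicted. The two folds' predictions are pooled —
#' every spectrum is predicted exactly once — into pooled accuracies and a
#' pooled confusion matrix.
#'
#' @param dataset A preprocessed [ap_spectra()].
#' @param condition `"RD"` (preprocessed only), `"FSD"` (+ feature mask)
#'   or `"DAD"` (+ mask + augmentation).
#' @param spec A [model_spec()].
#' @param seed Seed driving the split, the mask fit and the augmentation.
#' @param fs A [fs_config()].
#' @param aug An [augmentation_config()].
#' @return A list of class `ap_condition_result`: `accuracy`,
#'   `per_analyte`, `confusion`, `predictions`, `masks` (per fold),
#'   `condition`, `family`.
#' @export
run_condition <- function(dataset, condition = c("RD", "FSD", "DAD"), spec,
                          seed = 1L, fs = fs_config(),
                          aug = augmentation_config()) {
  condition <- match.arg(condition)
  halves <- split_train_test(dataset, seed)
  preds <- list()
  masks <- list()
  for (fold in 1:2) {
    tr <- if (fold == 1L) halves$train else halves$test
    te <- if (fold == 1L) halves$test else halves$train
    prep <- prepare_fold(tr, te, condition, fs, aug,
                         seed = derive_seed(seed, fold))
    sp <- spec
    sp$seed <- derive_seed(seed, 10L + fold)
    model <- tune_and_train(sp, prep$pool)
    preds[[fold]] <- predict_groups(model, prep$test)
    masks[[fold]] <- prep$mask
  }
  pooled <- do.call(rbind, preds)
  class(pooled) <- c("ap_predictions", "data.frame")
  structure(
    list(accuracy = accuracy(pooled, "group"),
         per_analyte = accuracy(pooled, "per_analyte"),
         confusion = confusion_matrix(pooled),
         predictions = pooled, masks = masks,
         condition = condition, family = spec$family),
    class = "ap_condition_result"
  )
}

#' Benchmark all conditions and model families
#'
#' The full experiment: RD vs FSD vs DAD for each requested family, under
#' the same split and swap protocol. Fold preparation (mask fitting,
#' augmentation) is shared across families within a condition, so every
#' family sees identical pools. A failing cell is recorded with its error
#' message and does not abort the others.
#'
#' @param dataset A preprocessed [ap_spectra()].
#' @param specs Named list of [model_spec()]s (default
#'   [default_model_specs()]).
#' @param conditions Character subset of c("RD", "FSD", "DAD").
#' @param seed Seed for the split and all fitted stages.
#' @param fs A [fs_config()].
#' @param aug An [augmentation_config()].
#' @return A list of class `ap_report`: `table` (data.frame condition x
#'   family with group-level and per-analyte accuracy), `confusions`
#'   (named list), `masks` (per condition/fold summaries), `errors`
#'   (failed cells), `seed`.
#' @export
run_benchmark <- function(dataset, specs = default_model_specs(),
                          conditions = c("RD", "FSD", "DAD"), seed = 1L,
                          fs = fs_config(), aug = augmentation_config()) {
  stopifnot(all(conditions %in% c("RD", "FSD", "DAD")))
  halves <- split_train_test(dataset, seed)
  cells <- list()
  confusions <- list()
  mask_info <- list()
  errors <- list()
  for (condition in conditions) {
    folds <- lapply(1:2, function(fold) {
      tr <- if (fold == 1L) halves$train else halves$test
      te <- if (fold == 1L) halves$test else halves$train
      prepare_fold(tr, te, condition, fs, aug, seed = derive_seed(seed, fold))
    })
    mask_info[[condition]] <- lapply(folds, function(f) {
      if (is.null(f$mask)) NULL else
        list(k = f$mask$k, dropped = f$mask$dropped_clusters,
             n_selected = length(f$mask$selected))
    })
    for (fam in names(specs)) {
      key <- paste(condition, fam, sep = ".")
      res <- tryCatch({
        preds <- lapply(1:2, function(fold) {
          sp <- specs[[fam]]
          sp$seed <- derive_seed(seed, 10L + fold)
          model <- tune_and_train(sp, folds[[fold]]$pool)
          predict_groups(model, folds[[fold]]$test)
        })
        pooled <- do.call(rbind, preds)
        class(pooled) <- c("ap_predictions", "data.frame")
        pooled
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
        next
      }
      cells[[key]] <- data.frame(
        condition = condition, family = fam,
        accuracy = accuracy(res, "group"),
        per_analyte = accuracy(res, "per_analyte"),
        n = nrow(res), stringsAsFactors = FALSE
      )
      confusions[[key]] <- confusion_matrix(res)
    }
  }
  structure(
    list(table = do.call(rbind, c(cells, list(make.row.names = FALSE))),
         confusions = confusions, masks = mask_info, errors = errors,
         seed = seed),
    class = "ap_report"
  )
}

#' @export
print.ap_report <- function(x, ...) {
  cat("<ap_report> accuracy by condition x family (seed", x$seed, ")\n")
  wide <- stats::reshape(
    x$table[, c("condition", "family", "accuracy")],
    idvar = "family", timevar = "condition", direction = "wide"
  )
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  if (length(x$errors)) {
    cat("failed cells:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-group error rates from a benchmark report
#'
#' For every (condition, family) cell, the fraction of each true group's
#' spectra that were misclassified (1 - diagonal / row sum of the
#' confusion matrix), plus the worst group per cell. The study's expected
#' pattern is that the ternary 1:1:1 mixture (group 7) is the hardest.
#'
#' @param report An [run_benchmark()] result.
#' @return A list: `errors` (data.frame condition, family, group,
#'   error_rate) and `worst` (data.frame with the highest-error group per
#'   cell).
#' @export
summarize_errors <- function(report) {
  stopifnot(inherits(report, "ap_report"))
  rows <- list()
  for (key in names(report$confusions)) {
    cm <- report$confusions[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    totals <- rowSums(cm)
    present <- which(totals > 0)
    rows[[key]] <- data.frame(
      condition = parts[1L], family = parts[2L],
      group = as.integer(rownames(cm)[present]),
      error_rate = 1 - diag(cm)[present] / totals[present],
      stringsAsFactors = FALSE
    )
  }
  errors <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  worst <- do.call(rbind, lapply(split(
    errors, paste(errors$condition, errors$family)
  ), function(d) d[which.max(d$error_rate), ]))
  rownames(worst) <- NULL
  list(errors = errors, worst = worst)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}
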