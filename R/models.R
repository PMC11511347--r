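#' Model specification
#'
#' A classifier family plus its hyperparameter grid for tuning. Grid
#' search is exhaustive over the cross product of the grid's value lists,
#' scored by mean accuracy over stratified cross-validation; ties break by
#' grid order.
#'
#' @param family One of `"LR"`, `"DT"`, `"kNN"`, `"LDA"`, `"SVM"`, `"RF"`,
#'   `"MLP"`.
#' @param grid Named list of hyperparameter value vectors (non-empty).
#'   Recognized names per family: LR `lambda` (ridge penalty of the
#'   multinomial logistic fit); DT `maxdepth`, `cp`; kNN `k`; LDA `tol`;
#'   SVM `cost`, `gamma` (NA = 1/p default); RF `num_trees`, `mtry`
#'   (NA = sqrt(p)); MLP `size`, `decay`, `maxit`.
#' @param cv_folds Stratified folds used when the grid has more than one
#'   point (default 5).
#' @param seed RNG seed for fold assignment and stochastic fits.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family, grid, cv_folds = 5L, seed = 1L) {
  families <- c("LR", "DT", "kNN", "LDA", "SVM", "RF", "MLP")
  if (!is.character(family) || length(family) != 1L || !family %in% families) {
    stop("unknown model family: ", paste(family, collapse = ","), call. = FALSE)
  }
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid)) ||
      any(!nzchar(names(grid))) || any(lengths(grid) == 0L)) {
    stop("grid must be a non-empty named list of value vectors", call. = FALSE)
  }
  stopifnot(cv_folds >= 2L)
  structure(
    list(family = family, grid = grid, cv_folds = as.integer(cv_folds),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Default single-point model specifications
#'
#' One compact, fixed hyperparameter point per family, chosen a priori as
#' standard small-data settings; used by the benchmark so that every
#' (condition, family) cell trains one model. Multi-point grids for
#' actual tuning are in [tuning_model_specs()].
#'
#' @param seed Seed stored in every spec.
#' @return Named list of [model_spec()]s for all seven families.
#' @export
default_model_specs <- function(seed = 1L) {
  list(
    LR  = model_spec("LR",  list(lambda = 0.01), seed = seed),
    DT  = model_spec("DT",  list(maxdepth = 8L, cp = 0.01), seed = seed),
    kNN = model_spec("kNN", list(k = 5L), seed = seed),
    LDA = model_spec("LDA", list(tol = 1e-9), seed = seed),
    SVM = model_spec("SVM", list(cost = 10, gamma = NA_real_), seed = seed),
    RF  = model_spec("RF",  list(num_trees = 200L, mtry = NA_real_), seed = seed),
    MLP = model_spec("MLP", list(size = 12L, decay = 1e-3, maxit = 150L),
                     seed = seed)
  )
}

#' Multi-point tuning grids
#'
#' Standard small-data sweep ranges for each family, for use with the
#' grid-search tuner when hyperparameter optimization is wanted.
#'
#' @param seed Seed stored in every spec.
#' @param cv_folds Stratified folds for tuning (default 5).
#' @return Named list of [model_spec()]s.
#' @export
tuning_model_specs <- function(seed = 1L, cv_folds = 5L) {
  list(
    LR  = model_spec("LR",  list(lambda = c(1e-3, 1e-2, 1e-1, 1)),
                     cv_folds, seed),
    DT  = model_spec("DT",  list(maxdepth = c(3L, 5L, 8L, 30L), cp = 0.01),
                     cv_folds, seed),
    kNN = model_spec("kNN", list(k = c(1L, 3L, 5L, 7L, 9L)), cv_folds, seed),
    LDA = model_spec("LDA", list(tol = c(1e-9, 1e-6)), cv_folds, seed),
    SVM = model_spec("SVM", list(cost = c(0.1, 1, 10, 100),
                                 gamma = NA_real_), cv_folds, seed),
    RF  = model_spec("RF",  list(num_trees = c(100L, 300L),
                                 mtry = NA_real_), cv_folds, seed),
    MLP = model_spec("MLP", list(size = c(8L, 12L, 24L), decay = c(1e-4, 1e-3),
                                 maxit = 150L), cv_folds, seed)
  )
}

# --- family fit/predict registry -------------------------------------------
# X: n x p numeric matrix; y: factor with the canonical group levels

fit_family <- function(family, X, y, params, seed) {
  set.seed(seed)
  p <- ncol(X)
  switch(family,
    LR = {
      # warm-start path down to the requested penalty; a cold single-lambda
      # multinomial fit converges poorly
      path <- exp(seq(log(params$lambda * 1e3), log(params$lambda),
                      length.out = 30L))
      list(fit = glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                                lambda = path),
           lambda = params$lambda)
    },
    DT = {
      df <- data.frame(.y = y, X)
      list(fit = rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(maxdepth = params$maxdepth,
                                       cp = if (is.null(params$cp)) 0.01 else params$cp,
                                       minsplit = 5L, minbucket = 2L,
                                       xval = 0L)
      ))
    },
    kNN = list(X = X, y = y, k = params$k),
    LDA = list(fit = suppressWarnings(
      MASS::lda(X, grouping = y,
                tol = if (is.null(params$tol)) 1e-9 else params$tol)
    )),
    SVM = {
      gamma <- params$gamma
      if (is.null(gamma) || is.na(gamma)) gamma <- 1 / p
      list(fit = e1071::svm(X, y, kernel = "radial", cost = params$cost,
                            gamma = gamma, scale = FALSE))
    },
    RF = {
      mtry <- params$mtry
      if (is.null(mtry) || is.na(mtry)) mtry <- max(1L, floor(sqrt(p)))
      list(fit = ranger::ranger(
        x = as.data.frame(X), y = y, num.trees = params$num_trees,
        mtry = min(mtry, p), seed = seed, num.threads = 1L
      ))
    },
    MLP = list(fit = nnet::nnet(
      x = X, y = nnet::class.ind(y), size = params$size, decay = params$decay,
      maxit = if (is.null(params$maxit)) 150L else params$maxit,
      softmax = TRUE, MaxNWts = 1e6, trace = FALSE
    ), levels = levels(y)),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

predict_family <- function(family, fitted, X, seed) {
  switch(family,
    LR = factor(drop(predict(fitted$fit, X, type = "class", s = fitted$lambda)),
                levels = fitted$fit$classnames),
    DT = predict(fitted$fit, newdata = as.data.frame(X), type = "class"),
    kNN = {
      set.seed(seed)  # vote ties in knn are broken at random
      class::knn(fitted$X, X, fitted$y, k = fitted$k, use.all = TRUE)
    },
    LDA = predict(fitted$fit, X)$class,
    SVM = predict(fitted$fit, X),
    RF = predict(fitted$fit, data = as.data.frame(X),
                 num.threads = 1L)$predictions,
    MLP = {
      prob <- predict(fitted$fit, X)
      factor(fitted$levels[max.col(prob, ties.method = "first")],
             levels = fitted$levels)
    },
    stop("unknown model family: ", family, call. = FALSE)
  )
}

# stratified fold ids, seeded
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Grid-search tuning and final fit
#'
#' Exhaustive grid search over the spec's hyperparameter grid, scored by
#' mean group-level accuracy over stratified `cv_folds`-fold
#' cross-validation on the pool; ties break by grid order, and a
#' single-point grid skips cross-validation entirely (equivalent to
#' direct training). The winning point is refitted on the full pool.
#'
#' @param spec A [model_spec()].
#' @param pool A labelled training [ap_spectra()] (spectra become rows of
#'   the design matrix).
#' @return A list of class `ap_model`: `family`, `params` (chosen point),
#'   `cv_accuracy` (NA for a singleton grid), `fitted`, `levels`,
#'   `n_features`, `seed`, `pool_fingerprint`.
#' @export
tune_and_train <- function(spec, pool) {
  stopifnot(inherits(spec, "model_spec"), inherits(pool, "ap_spectra"))
  X <- t(pool$intensities)
  colnames(X) <- paste0("s", seq_len(ncol(X)))
  y <- factor(pool$labels$group_id, levels = sort(unique(pool$labels$group_id)))
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cv_acc <- NA_real_
  if (nrow(grid) == 1L) {
    best <- 1L
  } else {
    counts <- table(y)
    if (any(counts < spec$cv_folds)) {
      stop("every group needs at least cv_folds points for tuning", call. = FALSE)
    }
    fold <- stratified_folds(y, spec$cv_folds, spec$seed)
    scores <- vapply(seq_len(nrow(grid)), function(gi) {
      params <- as.list(grid[gi, , drop = FALSE])
      accs <- vapply(seq_len(spec$cv_folds), function(f) {
        tr <- fold != f
        m <- fit_family(spec$family, X[tr, , drop = FALSE], droplevels(y[tr]),
                        params, spec$seed + f)
        pred <- predict_family(spec$family, m, X[!tr, , drop = FALSE],
                               spec$seed + f)
        mean(as.character(pred) == as.character(y[!tr]))
      }, 0)
      mean(accs)
    }, 0)
    best <- which.max(round(scores, 12L))
    cv_acc <- scores[best]
  }
  params <- as.list(grid[best, , drop = FALSE])
  fitted <- fit_family(spec$family, X, y, params, spec$seed)
  structure(
    list(family = spec$family, params = params, cv_accuracy = cv_acc,
         fitted = fitted, levels = levels(y), n_features = ncol(X),
         seed = spec$seed,
         pool_fingerprint = sprintf("%d spectra x %d features",
                                    nrow(X), ncol(X))),
    class = "ap_model"
  )
}

#' Predict mixing-ratio groups
#'
#' Predicts one group id per spectrum and derives the per-analyte
#' presence triplet through the fixed group-to-presence map.
#'
#' @param model An [tune_and_train()] result.
#' @param set An [ap_spectra()] with the feature dimension the model was
#'   trained on.
#' @return A data.frame of class `ap_predictions`: `id`, `truth`, `pred`
#'   (group ids) plus true/predicted presence columns.
#' @export
predict_groups <- function(model, set) {
  stopifnot(inherits(model, "ap_model"), inherits(set, "ap_spectra"))
  if (length(set$shifts) != model$n_features) {
    stop(sprintf("model expects %d features, set has %d",
                 model$n_features, length(set$shifts)), call. = FALSE)
  }
  X <- t(set$intensities)
  colnames(X) <- paste0("s", seq_len(ncol(X)))
  pred <- predict_family(model$family, model$fitted, X, model$seed)
  pred <- as.integer(as.character(pred))
  pres_true <- presence_from_group(set$labels$group_id)
  pres_pred <- presence_from_group(pred)
  out <- data.frame(
    id = set$labels$id,
    truth = set$labels$group_id,
    pred = pred,
    true_amp = pres_true[, "AMP"], true_adp = pres_true[, "ADP"],
    true_atp = pres_true[, "ATP"],
    pred_amp = pres_pred[, "AMP"], pred_adp = pres_pred[, "ADP"],
    pred_atp = pres_pred[, "ATP"],
    stringsAsFactors = FALSE
  )
  class(out) <- c("ap_predictions", "data.frame")
  out
}

#' Classification accuracy
#'
#' `level = "group"`: fraction of spectra whose predicted mixing-ratio
#' group is correct. `level = "per_analyte"`: fraction of correct
#' presence/absence bits over the three analytes (3 bits per spectrum).
#' Because each group has a distinct presence triplet, per-analyte
#' accuracy is always >= group accuracy.
#'
#' @param pred An [predict_groups()] result.
#' @param level `"group"` (default) or `"per_analyte"`.
#' @return A fraction in [0, 1].
#' @export
accuracy <- function(pred, level = c("group", "per_analyte")) {
  level <- match.arg(level)
  stopifnot(inherits(pred, "ap_predictions"))
  if (nrow(pred) == 0L) stop("empty prediction set", call. = FALSE)
  if (level == "group") {
    mean(pred$pred == pred$truth)
  } else {
    mean(c(pred$pred_amp == pred$true_amp,
           pred$pred_adp == pred$true_adp,
           pred$pred_atp == pred$true_atp))
  }
}

#' Confusion matrix over the seven mixing-ratio groups
#'
#' @param pred An [predict_groups()] result.
#' @return A 7 x 7 integer matrix, rows = true group, columns = predicted
#'   group; entries sum to `nrow(pred)`.
#' @export
confusion_matrix <- function(pred) {
  stopifnot(inherits(pred, "ap_predictions"))
  if (nrow(pred) == 0L) stop("empty prediction set", call. = FALSE)
  unclass(table(
    true = factor(pred$truth, levels = 1:7),
    predicted = factor(pred$pred, levels = 1:7)
  ))
}
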