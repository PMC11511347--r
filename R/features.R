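#' Shift-by-spectrum feature matrix
#'
#' The representation clustered during feature selection: one row per
#' Raman shift, one column per training spectrum, values the standardized
#' intensities. Shifts whose rows move together across spectra (bands, or
#' flat noise) end up in the same cluster.
#'
#' @param train A preprocessed [ap_spectra()] training set.
#' @return Numeric matrix (shifts x spectra) with attribute `"shifts"`.
#' @export
build_shift_matrix <- function(train) {
  stopifnot(inherits(train, "ap_spectra"))
  if (n_spectra(train) == 0L) stop("empty training set", call. = FALSE)
  m <- train$intensities
  attr(m, "shifts") <- train$shifts
  m
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[centers[1L], ], `-`)^2)
    for (i in 2L:k) {
      if (sum(d2) <= 0) {
        pool <- setdiff(seq_len(n), centers[seq_len(i - 1L)])
        centers[i] <- if (length(pool)) pool[sample.int(length(pool), 1L)] else
          sample.int(n, 1L)
      } else {
        centers[i] <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[i], ], `-`)^2))
    }
  }
  x[centers, , drop = FALSE]
}

# exact assignment when there are at most k distinct rows: one cluster per
# distinct row, duplicates split to fill k non-empty clusters, WCSS = 0
degenerate_kmeans <- function(x, k) {
  key <- apply(x, 1L, paste, collapse = "\r")
  labels <- match(key, unique(key))
  n_distinct <- max(labels)
  extra <- k - n_distinct
  while (extra > 0L) {
    counts <- tabulate(labels)
    big <- which.max(counts)
    idx <- which(labels == big)
    labels[idx[seq_len(length(idx) %/% 2L)]] <- max(labels) + 1L
    extra <- extra - 1L
  }
  centroids <- do.call(rbind, lapply(seq_len(k), function(c) {
    colMeans(x[labels == c, , drop = FALSE])
  }))
  list(k = k, labels = labels, centroids = centroids, wcss = 0)
}

#' Cluster Raman shifts by k-means
#'
#' Lloyd's algorithm (via [stats::kmeans()]) with k-means++ seeding, run
#' `n_init` times and keeping the restart with the lowest within-cluster
#' sum of squares. Deterministic for a fixed seed.
#'
#' @param matrix A [build_shift_matrix()] result (rows are clustered).
#' @param k Number of clusters, 1 <= k <= nrow(matrix).
#' @param seed RNG seed.
#' @param n_init Number of seeded restarts (default 10).
#' @return A list of class `cluster_assignment`: `k`, `labels` (cluster id
#'   per row, 1..k, every cluster non-empty), `centroids`, `wcss`.
#' @export
kmeans_shifts <- function(matrix, k, seed = 1L, n_init = 10L) {
  x <- unclass(matrix)
  n <- nrow(x)
  if (k < 1L || k > n) {
    stop(sprintf("k = %d outside 1..%d (number of shifts)", k, n), call. = FALSE)
  }
  set.seed(seed)
  if (nrow(unique(x)) <= k) {
    out <- degenerate_kmeans(x, k)
  } else {
    best <- NULL
    for (r in seq_len(n_init)) {
      km <- NULL
      for (attempt in 1:5) {
        km <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = kmeanspp_init(x, k),
                                         iter.max = 100L, algorithm = "Lloyd")),
          error = function(e) NULL
        )
        if (!is.null(km)) break
      }
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
    out <- list(k = k, labels = as.integer(best$cluster),
                centroids = unname(best$centers),
                wcss = best$tot.withinss)
  }
  attr(out, "shifts") <- attr(matrix, "shifts")
  class(out) <- "cluster_assignment"
  out
}

# elbow geometry: index maximizing perpendicular distance to the chord of
# the normalized (k, wcss) curve; ties and flat curves resolve to the
# smallest k
elbow_point <- function(ks, wcss) {
  stopifnot(length(ks) == length(wcss), length(ks) >= 2L)
  x <- (ks - ks[1L]) / (ks[length(ks)] - ks[1L])
  wrange <- max(wcss) - min(wcss)
  if (wrange <= 0) return(ks[1L])
  y <- (wcss - min(wcss)) / wrange
  x1 <- x[1L]; y1 <- y[1L]; x2 <- x[length(x)]; y2 <- y[length(y)]
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  ks[which.max(round(d, 12L))]
}

#' Choose the cluster count by the elbow method
#'
#' Computes the within-cluster sum of squares for k = 1..k_max (each by
#' best-of-restarts [kmeans_shifts()]) and selects the k whose point on
#' the WCSS curve, with both axes rescaled to [0, 1], lies farthest from
#' the chord joining the curve's endpoints. Ties break toward smaller k;
#' a perfectly straight curve yields k = 1.
#'
#' @param matrix A [build_shift_matrix()] result.
#' @param k_max Largest k swept (default 10; must be >= 2 and at most the
#'   row count).
#' @param seed RNG seed.
#' @param n_init Restarts per k.
#' @return A list: `k` (the chosen count) and `wcss` (named vector over
#'   the sweep).
#' @export
elbow_select_k <- function(matrix, k_max = 10L, seed = 1L, n_init = 10L) {
  n <- nrow(unclass(matrix))
  if (k_max < 2L) stop("k_max must be >= 2", call. = FALSE)
  if (k_max > n) stop("k_max exceeds the number of shifts", call. = FALSE)
  ks <- seq_len(k_max)
  wcss <- vapply(ks, function(k) {
    kmeans_shifts(matrix, k, seed = seed + k, n_init = n_init)$wcss
  }, 0)
  names(wcss) <- ks
  list(k = elbow_point(ks, wcss), wcss = wcss)
}

#' Rank clusters by class information and pick the noisiest
#'
#' A cluster of Raman shifts is "noise" when its shifts carry no
#' characteristic bands, i.e. no mixing-ratio-group dependence. Each
#' cluster is scored by the mean (over its shifts) of the between-group
#' variance of the per-group mean intensities at that shift; the `n_drop`
#' lowest-scoring clusters are returned (ties toward the smaller cluster
#' id).
#'
#' @param assignment A [kmeans_shifts()] result.
#' @param train The preprocessed training [ap_spectra()] the assignment
#'   was fitted on.
#' @param n_drop How many clusters to drop (0 <= n_drop < k).
#' @return Integer vector of dropped cluster ids (with the per-cluster
#'   scores as attribute `"scores"`).
#' @export
identify_noise_clusters <- function(assignment, train, n_drop = 1L) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(train, "ap_spectra"))
  if (n_drop >= assignment$k) {
    stop("n_drop must be smaller than the number of clusters", call. = FALSE)
  }
  groups <- sort(unique(train$labels$group_id))
  gm <- vapply(groups, function(g) {
    rowMeans(train$intensities[, train$labels$group_id == g, drop = FALSE])
  }, numeric(length(train$shifts)))
  shift_score <- apply(gm, 1L, stats::var)
  scores <- vapply(seq_len(assignment$k), function(c) {
    mean(shift_score[assignment$labels == c])
  }, 0)
  dropped <- if (n_drop == 0L) integer(0) else
    order(scores, seq_along(scores))[seq_len(n_drop)]
  attr(dropped, "scores") <- scores
  dropped
}

#' Fit a feature mask on training spectra
#'
#' The full feature-selection procedure: build the shift-by-spectrum
#' matrix, choose k by the elbow method, cluster the shifts with k-means,
#' and drop the `n_drop` least class-informative clusters. Only the
#' training set is inspected; the mask is then applied unchanged to any
#' set on the same grid.
#'
#' @param train A preprocessed [ap_spectra()] training set.
#' @param k_max Elbow sweep upper bound (default 10).
#' @param n_drop Clusters to remove (default 1).
#' @param seed RNG seed.
#' @param n_init k-means restarts.
#' @return A list of class `feature_mask`: `selected` (integer indices of
#'   retained shifts), `selected_shifts` (their cm^-1 values),
#'   `dropped_clusters`, `assignment`, `k`, `grid`.
#' @export
select_features <- function(train, k_max = 10L, n_drop = 1L, seed = 1L,
                            n_init = 10L) {
  m <- build_shift_matrix(train)
  elbow <- elbow_select_k(m, k_max = k_max, seed = seed, n_init = n_init)
  assignment <- kmeans_shifts(m, elbow$k, seed = seed + elbow$k, n_init = n_init)
  dropped <- identify_noise_clusters(assignment, train, n_drop = n_drop)
  selected <- which(!assignment$labels %in% dropped)
  if (length(selected) == 0L) stop("feature mask would be empty", call. = FALSE)
  structure(
    list(selected = selected, selected_shifts = train$shifts[selected],
         dropped_clusters = as.integer(dropped), assignment = assignment,
         k = elbow$k, wcss = elbow$wcss, grid = train$shifts),
    class = "feature_mask"
  )
}

#' Apply a fitted feature mask
#'
#' Restricts every spectrum to the mask's retained shifts. The same mask
#' is applied to training and test sets; it is never refitted here.
#'
#' @param set An [ap_spectra()] on the grid the mask was fitted on.
#' @param mask A [select_features()] result.
#' @return The masked `ap_spectra`; labels untouched.
#' @export
apply_mask <- function(set, mask) {
  stopifnot(inherits(set, "ap_spectra"), inherits(mask, "feature_mask"))
  if (!isTRUE(all.equal(set$shifts, mask$grid))) {
    stop("set grid does not match the grid the mask was fitted on", call. = FALSE)
  }
  out <- set
  out$shifts <- set$shifts[mask$selected]
  out$intensities <- set$intensities[mask$selected, , drop = FALSE]
  out
}
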