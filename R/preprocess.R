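#' Preprocessing configuration
#'
#' Parameters of the spectrum-conditioning chain applied before any
#' learning: fingerprint-region crop, iterative quintic baseline
#' correction, Savitzky-Golay smoothing (window 5, degree 2) and
#' per-spectrum standardization.
#'
#' @param crop_lo,crop_hi Fingerprint-region bounds in cm^-1
#'   (defaults 200, 1700).
#' @param baseline_degree Baseline polynomial degree (default 5, a
#'   quintic).
#' @param sg_window Savitzky-Golay window length in points (odd,
#'   default 5).
#' @param sg_degree Savitzky-Golay polynomial degree (default 2; must be
#'   less than `sg_window`).
#' @param baseline_max_iter Iteration cap for the peak-suppressed baseline
#'   fit (default 100).
#' @param baseline_tol Relative coefficient-change convergence tolerance
#'   (default 1e-4).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_lo = 200, crop_hi = 1700,
                              baseline_degree = 5L,
                              sg_window = 5L, sg_degree = 2L,
                              baseline_max_iter = 100L, baseline_tol = 1e-4) {
  stopifnot(crop_lo < crop_hi, baseline_degree >= 0,
            baseline_max_iter >= 1, baseline_tol > 0)
  if (sg_window %% 2L == 0L || sg_window <= sg_degree) {
    stop("sg_window must be odd and greater than sg_degree", call. = FALSE)
  }
  structure(
    list(crop_lo = crop_lo, crop_hi = crop_hi,
         baseline_degree = as.integer(baseline_degree),
         sg_window = as.integer(sg_window), sg_degree = as.integer(sg_degree),
         baseline_max_iter = as.integer(baseline_max_iter),
         baseline_tol = baseline_tol),
    class = "preprocess_config"
  )
}

#' Crop a spectrum set to a shift window
#'
#' Keeps exactly the grid points with `lo <= shift <= hi` (closed
#' interval), preserving order.
#'
#' @param set An [ap_spectra()].
#' @param lo,hi Window bounds in cm^-1.
#' @return The cropped `ap_spectra`.
#' @export
crop_spectra <- function(set, lo = 200, hi = 1700) {
  stopifnot(inherits(set, "ap_spectra"), lo < hi)
  keep <- set$shifts >= lo & set$shifts <= hi
  if (!any(keep)) {
    stop(sprintf("crop window [%g, %g] cm^-1 contains no grid points", lo, hi),
         call. = FALSE)
  }
  out <- set
  out$shifts <- set$shifts[keep]
  out$intensities <- set$intensities[keep, , drop = FALSE]
  out
}

#' Iterative polynomial baseline correction
#'
#' Estimates a smooth polynomial background (degree 5 by default) by
#' peak-suppressed iterative least squares in the ModPoly style: fit the
#' polynomial, clip the working signal at the fit wherever it exceeds the
#' fit (suppressing peaks), refit, and repeat until the maximum relative
#' coefficient change drops below `baseline_tol` or `baseline_max_iter` is
#' reached. The converged baseline is subtracted from the original
#' intensities. Fitting uses an orthogonal polynomial basis on the shift
#' grid rescaled to [-1, 1] for numerical stability; the procedure is
#' deterministic.
#'
#' @param intensities Numeric intensity vector.
#' @param shifts Matching Raman-shift grid.
#' @param config A [preprocess_config()].
#' @return Baseline-corrected intensity vector, with the fitted baseline
#'   attached as attribute `"baseline"`.
#' @export
correct_baseline <- function(intensities, shifts, config = preprocess_config()) {
  deg <- config$baseline_degree
  n <- length(intensities)
  stopifnot(length(shifts) == n)
  if (n < deg + 1L) {
    stop(sprintf("need at least %d points for a degree-%d baseline", deg + 1L, deg),
         call. = FALSE)
  }
  u <- 2 * (shifts - min(shifts)) / (max(shifts) - min(shifts)) - 1
  basis <- cbind(1, if (deg > 0L) stats::poly(u, degree = deg) else NULL)
  yw <- intensities
  coef_old <- NULL
  baseline <- NULL
  for (it in seq_len(config$baseline_max_iter)) {
    fit <- stats::lm.fit(basis, yw)
    baseline <- drop(basis %*% fit$coefficients)
    if (!is.null(coef_old)) {
      scale <- max(abs(fit$coefficients), .Machine$double.eps)
      if (max(abs(fit$coefficients - coef_old)) / scale < config$baseline_tol) break
    }
    coef_old <- fit$coefficients
    yw <- pmin(yw, baseline)
  }
  out <- intensities - baseline
  attr(out, "baseline") <- baseline
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with the configured window and
#' degree (defaults 5 and 2). Edges are handled by the edge rows of the
#' Savitzky-Golay projection matrix (a polynomial fit over the edge
#' window), so the output has the same length as the input and any
#' polynomial of degree <= `sg_degree` passes through unchanged.
#'
#' @param intensities Numeric intensity vector of length >= `sg_window`.
#' @param config A [preprocess_config()].
#' @return Smoothed intensity vector.
#' @export
smooth_sg <- function(intensities, config = preprocess_config()) {
  if (length(intensities) < config$sg_window) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(intensities, p = config$sg_degree,
                                n = config$sg_window))
}

#' Standardize a spectrum to mean 0, sd 1
#'
#' Per-spectrum standardization I_std = (I - mean(I)) / sd(I) with the
#' sample standard deviation (n - 1 denominator), aligning the intensity
#' scale across spectra whose absolute SERS intensity depends on substrate
#' and measurement conditions.
#'
#' @param intensities Numeric vector of length >= 2 with positive
#'   variance.
#' @return The standardized vector, with attribute `"stats"` =
#'   `list(mean, sd)`.
#' @export
#' @examples
#' standardize(c(1, 2, 3))
standardize <- function(intensities) {
  if (length(intensities) < 2L) stop("need at least 2 points", call. = FALSE)
  m <- mean(intensities)
  s <- stats::sd(intensities)
  # relative threshold: float dust left on a constant signal (e.g. by the
  # smoothing convolution) must not pass as variance
  if (!is.finite(s) || s <= 1e-10 * max(abs(m), .Machine$double.eps)) {
    stop("zero-variance spectrum cannot be standardized", call. = FALSE)
  }
  out <- (intensities - m) / s
  attr(out, "stats") <- list(mean = m, sd = s)
  out
}

#' Preprocess a spectrum set
#'
#' Applies the full conditioning chain per spectrum, in order: crop to the
#' fingerprint window, baseline correction, Savitzky-Golay smoothing,
#' standardization. Each spectrum is processed independently of the others
#' (no cross-spectrum statistics), labels and spectrum order are
#' preserved.
#'
#' @param set An [ap_spectra()].
#' @param config A [preprocess_config()].
#' @param baseline,smooth Logical switches to disable the baseline or
#'   smoothing stage (both TRUE by default).
#' @return The preprocessed `ap_spectra`; every spectrum has mean 0 and
#'   sd 1.
#' @export
preprocess_set <- function(set, config = preprocess_config(),
                           baseline = TRUE, smooth = TRUE) {
  stopifnot(inherits(set, "ap_spectra"))
  if (n_spectra(set) == 0L) return(set)
  out <- crop_spectra(set, config$crop_lo, config$crop_hi)
  for (j in seq_len(n_spectra(out))) {
    y <- out$intensities[, j]
    res <- tryCatch({
      if (baseline) y <- as.numeric(correct_baseline(y, out$shifts, config))
      if (smooth) y <- smooth_sg(y, config)
      as.numeric(standardize(y))
    }, error = function(e) {
      stop(sprintf("spectrum '%s': %s", out$labels$id[j], conditionMessage(e)),
           call. = FALSE)
    })
    out$intensities[, j] <- res
  }
  out
}
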