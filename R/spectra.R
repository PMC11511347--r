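#' Labelled SERS spectrum set
#'
#' The container every pipeline stage consumes and returns: a set of
#' spectra on a shared Raman-shift grid, stored wide (one column per
#' spectrum), with one row of labels per spectrum.
#'
#' @param shifts Strictly increasing numeric Raman-shift grid (cm^-1).
#' @param intensities Numeric matrix, `length(shifts)` rows, one column per
#'   spectrum (arbitrary units).
#' @param labels A data.frame with one row per spectrum and columns
#'   `id` (character, unique), `group_id` (integer 1-7), `ratio_amp`,
#'   `ratio_adp`, `ratio_atp` (numeric), `presence_amp`, `presence_adp`,
#'   `presence_atp` (logical), `origin` (character: "measured", "noise" or
#'   "smote"), `source_id` (character; the spectrum a synthetic point was
#'   derived from, or NA).
#' @return An object of class `ap_spectra`.
#' @export
ap_spectra <- function(shifts, intensities, labels) {
  shifts <- as.numeric(shifts)
  intensities <- as.matrix(intensities)
  if (length(shifts) == 0L) stop("empty shift grid", call. = FALSE)
  if (any(diff(shifts) <= 0)) stop("shifts must be strictly increasing", call. = FALSE)
  if (nrow(intensities) != length(shifts)) {
    stop("intensities must have one row per Raman shift", call. = FALSE)
  }
  if (anyNA(intensities)) stop("intensities contain missing values", call. = FALSE)
  required <- c(
    "id", "group_id", "ratio_amp", "ratio_adp", "ratio_atp",
    "presence_amp", "presence_adp", "presence_atp", "origin", "source_id"
  )
  missing_cols <- setdiff(required, names(labels))
  if (length(missing_cols)) {
    stop("labels lack column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(labels) != ncol(intensities)) {
    stop("labels must have one row per spectrum", call. = FALSE)
  }
  if (anyDuplicated(labels$id)) stop("spectrum ids must be unique", call. = FALSE)
  ratios <- as.matrix(labels[, c("ratio_amp", "ratio_adp", "ratio_atp")])
  pres <- as.matrix(labels[, c("presence_amp", "presence_adp", "presence_atp")])
  if (!all((ratios > 0) == pres)) {
    stop("presence labels inconsistent with ratios (presence <=> ratio > 0)", call. = FALSE)
  }
  colnames(intensities) <- labels$id
  rownames(labels) <- NULL
  structure(
    list(shifts = shifts, intensities = intensities, labels = labels),
    class = "ap_spectra"
  )
}

#' @export
print.ap_spectra <- function(x, ...) {
  cat(sprintf(
    "<ap_spectra> %d spectra x %d shifts (%.0f-%.0f cm^-1)\n",
    n_spectra(x), length(x$shifts), min(x$shifts), max(x$shifts)
  ))
  tab <- table(x$labels$group_id)
  cat("  groups:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  org <- table(x$labels$origin)
  cat("  origin:", paste(sprintf("%s:%d", names(org), org), collapse = " "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set An `ap_spectra` object.
#' @return Integer count.
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "ap_spectra"))
  ncol(set$intensities)
}

#' Subset a spectrum set by spectrum index
#' @param set An `ap_spectra` object.
#' @param idx Integer or logical index over spectra (columns).
#' @return An `ap_spectra` with the selected spectra, order as in `idx`.
#' @export
subset_spectra <- function(set, idx) {
  stopifnot(inherits(set, "ap_spectra"))
  ap_spectra(set$shifts, set$intensities[, idx, drop = FALSE],
             set$labels[idx, , drop = FALSE])
}

#' Concatenate spectrum sets sharing a grid
#' @param ... `ap_spectra` objects on identical grids with disjoint ids.
#' @return The combined `ap_spectra`.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, n_spectra, 1L) > 0L]
  stopifnot(length(sets) >= 1L)
  for (s in sets[-1L]) {
    if (!isTRUE(all.equal(s$shifts, sets[[1L]]$shifts))) {
      stop("cannot bind spectrum sets on different grids", call. = FALSE)
    }
  }
  ap_spectra(
    sets[[1L]]$shifts,
    do.call(cbind, lapply(sets, `[[`, "intensities")),
    do.call(rbind, lapply(sets, `[[`, "labels"))
  )
}

# labels row constructor shared by the generator and the augmenters
ap_labels <- function(id, group_id, ratio, origin = "measured", source_id = NA_character_) {
  data.frame(
    id = id,
    group_id = as.integer(group_id),
    ratio_amp = ratio[1L], ratio_adp = ratio[2L], ratio_atp = ratio[3L],
    presence_amp = ratio[1L] > 0,
    presence_adp = ratio[2L] > 0,
    presence_atp = ratio[3L] > 0,
    origin = origin,
    source_id = source_id,
    stringsAsFactors = FALSE
  )
}
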