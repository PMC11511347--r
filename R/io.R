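#' Write a spectrum set as wide CSV plus JSON sidecar
#'
#' The interchange format of the pipeline: `<prefix>.csv` holds a
#' `raman_shift_cm-1` column followed by one intensity column per spectrum
#' (named by spectrum id), and `<prefix>.json` holds the per-spectrum
#' labels (group, ratio, presence, origin, source) and, when present, the
#' generator configuration including its seed.
#'
#' @param set An [ap_spectra()].
#' @param prefix File path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_spectra <- function(set, prefix) {
  stopifnot(inherits(set, "ap_spectra"))
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  df <- data.frame(`raman_shift_cm-1` = set$shifts, check.names = FALSE)
  df <- cbind(df, as.data.frame(set$intensities, check.names = FALSE))
  utils::write.csv(df, csv, row.names = FALSE)
  config <- attr(set, "config")
  sidecar <- list(labels = set$labels)
  if (!is.null(config)) {
    sidecar$config <- unclass(config)
    sidecar$config$ratios <- unname(apply(config$ratios, 1L, as.numeric,
                                          simplify = FALSE))
    sidecar$config$baseline_coeff_ranges <-
      unname(apply(config$baseline_coeff_ranges, 1L, as.numeric,
                   simplify = FALSE))
  }
  jsonlite::write_json(sidecar, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' Read a spectrum set written by [write_spectra()]
#'
#' @param prefix File path prefix (without extension).
#' @return The reconstructed [ap_spectra()] (labels only; a stored
#'   generator config is attached as attribute `"config_json"`).
#' @export
read_spectra <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  labels <- as.data.frame(sidecar$labels, stringsAsFactors = FALSE)
  for (col in c("id", "origin", "source_id")) {
    labels[[col]] <- as.character(labels[[col]])
  }
  labels$group_id <- as.integer(labels$group_id)
  set <- ap_spectra(
    shifts = df[["raman_shift_cm-1"]],
    intensities = as.matrix(df[, labels$id, drop = FALSE]),
    labels = labels
  )
  if (!is.null(sidecar$config)) attr(set, "config_json") <- sidecar$config
  set
}
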