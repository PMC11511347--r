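#' Canonical AMP:ADP:ATP mixing ratios
#'
#' The seven volume mixing ratios of AMP:ADP:ATP measured in the study
#' design this package reproduces: the three pure solutions, the three
#' pairwise 1:1 mixtures and the ternary 1:1:1 mixture. Group ids 1-7 index
#' the rows.
#'
#' @return A 7 x 3 numeric matrix with columns `AMP`, `ADP`, `ATP` and
#'   rownames `"1"`..`"7"`; each row is a (relative volume) mixing ratio.
#' @export
#' @examples
#' ap_mixing_ratios()
ap_mixing_ratios <- function() {
  m <- rbind(
    c(1, 0, 0),
    c(0, 1, 0),
    c(0, 0, 1),
    c(1, 1, 0),
    c(1, 0, 1),
    c(0, 1, 1),
    c(1, 1, 1)
  )
  dimnames(m) <- list(as.character(1:7), c("AMP", "ADP", "ATP"))
  m
}

#' Presence triplet for a mixing-ratio group
#'
#' Maps group ids to the presence/absence triplet of each adenosine
#' phosphate. Presence of component c is defined as ratio[c] > 0, so the
#' map is injective over the seven canonical ratio patterns: group-level
#' predictions determine per-analyte predictions.
#'
#' @param group_id Integer vector of group ids in 1..7.
#' @return A logical matrix with one row per input id and columns
#'   `AMP`, `ADP`, `ATP`.
#' @export
#' @examples
#' presence_from_group(c(1, 7))
presence_from_group <- function(group_id) {
  group_id <- as.integer(group_id)
  if (any(is.na(group_id)) || any(group_id < 1L) || any(group_id > 7L)) {
    stop("group_id must be in 1..7", call. = FALSE)
  }
  (ap_mixing_ratios() > 0)[group_id, , drop = FALSE]
}

#' Group id for a mixing ratio
#'
#' @param ratio Numeric length-3 ratio (AMP, ADP, ATP). Matched by its
#'   nonzero pattern against the canonical seven ratios.
#' @return Integer group id in 1..7.
#' @export
group_from_ratio <- function(ratio) {
  stopifnot(length(ratio) == 3L, all(ratio >= 0))
  if (all(ratio == 0)) stop("all-zero mixing ratio has no group", call. = FALSE)
  pattern <- ratio > 0
  canon <- ap_mixing_ratios() > 0
  hit <- which(apply(canon, 1L, function(p) all(p == pattern)))
  if (length(hit) != 1L) stop("ratio pattern not among the 7 canonical groups", call. = FALSE)
  as.integer(hit)
}
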