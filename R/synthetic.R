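#' Configuration for the synthetic SERS generator
#'
#' Defines the forward model used to emulate SERS spectra of AMP/ADP/ATP
#' mixtures: a shared Raman-shift grid, per-species band dictionaries,
#' a smooth quintic background, per-spectrum multiplicative enhancement
#' variability (SERS intensity depends strongly on substrate and focus),
#' and additive white noise. Defaults define the study conditions used
#' throughout the package: 7 mixing-ratio groups x 20 replicates = 140
#' spectra on a 200-1700 cm^-1 fingerprint grid.
#'
#' @param grid_lo,grid_hi,grid_step Raman-shift grid bounds and step
#'   (cm^-1). Default 200-1700 at 4 cm^-1 (376 points), a typical
#'   dispersive-CCD pixel spacing that keeps the 5-point smoothing window
#'   (16 cm^-1) narrower than the narrowest band (20 cm^-1 FWHM).
#' @param replicates_per_ratio Spectra generated per mixing ratio
#'   (default 20).
#' @param ratios Matrix of mixing ratios, one row per group
#'   (default [ap_mixing_ratios()]).
#' @param baseline_coeff_ranges 6 x 2 matrix of (min, max) ranges for the
#'   quintic baseline coefficients c0..c5, applied on the shift grid
#'   rescaled to [-1, 1]. Each spectrum draws its own coefficients
#'   uniformly, so the background varies from spectrum to spectrum but is
#'   always exactly removable by a quintic fit.
#' @param enhancement_sd Log-scale sd of the per-spectrum multiplicative
#'   enhancement factor exp(N(0, enhancement_sd)); models substrate- and
#'   measurement-dependent SERS intensity.
#' @param noise_sd Additive white-noise sd, relative to the maximum clean
#'   band amplitude. The default 0.025 is the generator's calibration
#'   constant: it places the feature-selected + augmented MLP pipeline in
#'   the 0.85-0.95 pooled-accuracy band, the small-data difficulty regime
#'   the pipeline is designed for.
#' @param adenine_offsets Named numeric, per-species rigid shift (cm^-1)
#'   of the adenine band centers, default c(AMP = 0, ADP = 3, ATP = 4).
#'   Species spectra differ slightly; offsets must stay within 5 cm^-1.
#' @param peak_shape `"lorentzian"` (default; the usual Raman line shape)
#'   or `"gaussian"`.
#' @param seed RNG seed used by [generate_dataset()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_lo = 200, grid_hi = 1700, grid_step = 4,
                             replicates_per_ratio = 20,
                             ratios = ap_mixing_ratios(),
                             baseline_coeff_ranges = default_baseline_ranges(),
                             enhancement_sd = 0.25,
                             noise_sd = 0.025,
                             adenine_offsets = c(AMP = 0, ADP = 3, ATP = 4),
                             peak_shape = c("lorentzian", "gaussian"),
                             seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  stopifnot(grid_lo < grid_hi, grid_step > 0, replicates_per_ratio >= 1)
  ratios <- as.matrix(ratios)
  stopifnot(ncol(ratios) == 3L, all(ratios >= 0), all(rowSums(ratios) > 0))
  baseline_coeff_ranges <- as.matrix(baseline_coeff_ranges)
  stopifnot(nrow(baseline_coeff_ranges) == 6L, ncol(baseline_coeff_ranges) == 2L,
            all(baseline_coeff_ranges[, 1L] <= baseline_coeff_ranges[, 2L]))
  stopifnot(enhancement_sd >= 0, noise_sd >= 0)
  stopifnot(all(abs(adenine_offsets) <= 5),
            all(c("AMP", "ADP", "ATP") %in% names(adenine_offsets)))
  structure(
    list(
      grid_lo = grid_lo, grid_hi = grid_hi, grid_step = grid_step,
      replicates_per_ratio = as.integer(replicates_per_ratio),
      ratios = ratios,
      baseline_coeff_ranges = baseline_coeff_ranges,
      enhancement_sd = enhancement_sd, noise_sd = noise_sd,
      adenine_offsets = adenine_offsets, peak_shape = peak_shape,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Default quintic-baseline coefficient ranges
#'
#' Intensities are in units of the strongest clean band (amplitude 1), so
#' the default background sits at 0.5-2 band-units with gentle curvature.
#'
#' @return A 6 x 2 matrix of (min, max) per coefficient degree 0..5.
#' @export
default_baseline_ranges <- function() {
  m <- rbind(c(0.5, 2.0), matrix(rep(c(-0.3, 0.3), 5L), ncol = 2L, byrow = TRUE))
  dimnames(m) <- list(paste0("c", 0:5), c("min", "max"))
  m
}

#' Shift grid of a synthetic configuration
#' @param config A `synthetic_config`.
#' @return Numeric vector of Raman shifts (cm^-1).
#' @export
config_grid <- function(config) {
  seq(config$grid_lo, config$grid_hi, by = config$grid_step)
}

#' Band dictionary for one adenosine phosphate
#'
#' Builds the default SERS band set of a species: the three adenine-moiety
#' bands near 730, 1330 and 1460 cm^-1 (ring breathing the strongest;
#' shared by all three species up to the configured small center offsets,
#' since the adenine moiety is what adsorbs to the substrate) plus the
#' phosphate-sensitive bands near 1075 and 1180 cm^-1 whose amplitudes
#' scale with the number of phosphate groups (1, 2 or 3).
#'
#' @param species `"AMP"`, `"ADP"` or `"ATP"`.
#' @param config A [synthetic_config()].
#' @return A list of class `species_profile` with elements `species`,
#'   `phosphate_count` and `bands` (data.frame: center, width = FWHM,
#'   amplitude, shape, moiety).
#' @export
#' @examples
#' species_profile("ATP", synthetic_config())$bands
species_profile <- function(species, config = synthetic_config()) {
  counts <- c(AMP = 1L, ADP = 2L, ATP = 3L)
  if (!is.character(species) || length(species) != 1L || !species %in% names(counts)) {
    stop("unknown species tag: ", paste(species, collapse = ","), call. = FALSE)
  }
  off <- config$adenine_offsets[[species]]
  npho <- counts[[species]]
  bands <- rbind(
    data.frame(
      center = c(730, 1330, 1460) + off,
      width = c(20, 26, 26),
      amplitude = c(1.00, 0.55, 0.40),
      moiety = "adenine"
    ),
    data.frame(
      center = c(1075, 1180),
      width = c(24, 24),
      amplitude = c(0.09, 0.11) * npho,
      moiety = "phosphate"
    )
  )
  bands$shape <- config$peak_shape
  stopifnot(all(bands$center >= 200 & bands$center <= 1700),
            all(bands$width > 0), all(bands$amplitude >= 0))
  structure(
    list(species = species, phosphate_count = npho, bands = bands),
    class = "species_profile"
  )
}

# evaluate one peak profile on a grid; amplitude is the height at center
eval_band <- function(shifts, center, width, amplitude, shape) {
  if (shape == "lorentzian") {
    hwhm <- width / 2
    amplitude * hwhm^2 / ((shifts - center)^2 + hwhm^2)
  } else {
    amplitude * exp(-4 * log(2) * (shifts - center)^2 / width^2)
  }
}

#' Noise-free spectrum of a mixture
#'
#' The clean forward model: intensity at each grid point is the
#' ratio-fraction-weighted sum of the species band sums. No baseline, no
#' noise, no enhancement factor.
#'
#' @param ratio Numeric length-3 mixing ratio (AMP, ADP, ATP); normalized
#'   internally to fractions over its nonzero components.
#' @param profiles Named list of [species_profile()]s for `AMP`, `ADP`,
#'   `ATP`.
#' @param shifts Raman-shift grid to evaluate on.
#' @return Numeric intensity vector, one value per shift; nonnegative.
#' @export
render_clean_spectrum <- function(ratio, profiles, shifts) {
  stopifnot(length(ratio) == 3L, all(ratio >= 0))
  if (sum(ratio) == 0) stop("all-zero mixing ratio", call. = FALSE)
  frac <- ratio / sum(ratio)
  species <- c("AMP", "ADP", "ATP")
  out <- numeric(length(shifts))
  for (i in seq_along(species)) {
    if (frac[i] == 0) next
    b <- profiles[[species[i]]]$bands
    for (r in seq_len(nrow(b))) {
      out <- out + frac[i] *
        eval_band(shifts, b$center[r], b$width[r], b$amplitude[r], b$shape[r])
    }
  }
  out
}

# quintic background on the grid rescaled to [-1, 1]
eval_baseline <- function(shifts, coeffs) {
  u <- 2 * (shifts - min(shifts)) / (max(shifts) - min(shifts)) - 1
  drop(outer(u, 0:5, `^`) %*% coeffs)
}

#' Generate a labelled synthetic SERS dataset
#'
#' For each mixing-ratio group, draws `replicates_per_ratio` spectra as
#'
#'   enhancement x clean(ratio) + quintic baseline + white noise,
#'
#' with the enhancement factor log-normal per spectrum, the quintic
#' coefficients uniform per spectrum from the configured ranges, and the
#' noise sd fixed relative to the maximum clean band amplitude. The
#' 200-650 and ~1520-1700 cm^-1 stretches carry no bands, so a pure-noise
#' region exists for feature selection to find. Bitwise reproducible for
#' a fixed config (the seed lives in the config).
#'
#' @param config A [synthetic_config()].
#' @return An [ap_spectra()] with `nrow(ratios) * replicates_per_ratio`
#'   spectra, ids `g<group>_r<replicate>`.
#' @export
#' @examples
#' set <- generate_dataset(synthetic_config(replicates_per_ratio = 2))
#' n_spectra(set)
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  shifts <- config_grid(config)
  profiles <- lapply(
    stats::setNames(nm = c("AMP", "ADP", "ATP")),
    species_profile, config = config
  )
  clean <- lapply(seq_len(nrow(config$ratios)), function(g) {
    render_clean_spectrum(config$ratios[g, ], profiles, shifts)
  })
  max_amp <- max(vapply(clean, max, 0))
  rng <- config$baseline_coeff_ranges
  cols <- list()
  labs <- list()
  for (g in seq_len(nrow(config$ratios))) {
    for (r in seq_len(config$replicates_per_ratio)) {
      enh <- exp(stats::rnorm(1L, 0, config$enhancement_sd))
      coeffs <- stats::runif(6L, rng[, 1L], rng[, 2L])
      eps <- stats::rnorm(length(shifts), 0, config$noise_sd * max_amp)
      y <- enh * clean[[g]] + eval_baseline(shifts, coeffs) + eps
      id <- sprintf("g%d_r%d", g, r)
      cols[[id]] <- y
      labs[[id]] <- ap_labels(id, g, config$ratios[g, ])
    }
  }
  set <- ap_spectra(shifts, do.call(cbind, cols), do.call(rbind, labs))
  attr(set, "config") <- config
  set
}
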