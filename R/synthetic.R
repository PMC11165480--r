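#' Initial-velocity assay design
#'
#' Describes a synthetic substrate-gradient assay matching the phosphatase
#' characterization conditions: a concentration grid inside 1-80 mM
#' (default `{1, 2, 5, 10, 20, 40, 80}`), 0.1-1 µM enzyme, replicated
#' wells, and a noise model. Noise is multiplicative Gaussian by default
#' (`noise_cv`, a coefficient of variation — velocities span an order of
#' magnitude across the grid, so relative error is the natural scale);
#' `noise_sd` switches to additive Gaussian.
#'
#' @param substrate_grid Substrate concentrations, mM; must lie in
#'   `[1, 80]` unless `allow_outside_range = TRUE`.
#' @param replicates Replicates per concentration (default 3).
#' @param enzyme_conc Enzyme concentration, µM (default 0.5).
#' @param noise_cv Multiplicative noise CV (default 0.06).
#' @param noise_sd Optional additive noise SD (overrides `noise_cv`).
#' @param seed RNG seed for generation.
#' @param allow_outside_range Permit grid points outside the assay range.
#' @return An `assay_design` list.
#' @export
assay_design <- function(substrate_grid = c(1, 2, 5, 10, 20, 40, 80),
                         replicates = 3, enzyme_conc = 0.5,
                         noise_cv = 0.06, noise_sd = NULL, seed = 1,
                         allow_outside_range = FALSE) {
  if (!allow_outside_range &&
      (any(substrate_grid < 1) || any(substrate_grid > 80))) {
    abort("substrate grid outside the 1-80 mM assay range; set `allow_outside_range = TRUE` to override.",
          class = "phosflux_config_error")
  }
  if (replicates < 1) {
    abort("`replicates` must be >= 1.", class = "phosflux_config_error")
  }
  if (enzyme_conc < 0.1 - 1e-12 || enzyme_conc > 1 + 1e-12) {
    abort("`enzyme_conc` must lie in [0.1, 1] µM.",
          class = "phosflux_config_error")
  }
  if (noise_cv < 0 || (!is.null(noise_sd) && noise_sd < 0)) {
    abort("noise parameters must be non-negative.",
          class = "phosflux_config_error")
  }
  structure(
    list(substrate_grid = sort(unique(substrate_grid)),
         replicates = as.integer(replicates), enzyme_conc = enzyme_conc,
         noise_cv = noise_cv, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "assay_design")
}

#' Generate a synthetic initial-velocity dataset
#'
#' Forward-simulates the Michaelis-Menten curve on the design grid, adds the
#' design's noise, and returns a tidy velocity table. The generating
#' parameters, seed, and the count of negative velocities truncated to 0
#' are attached as the `"ground_truth"` attribute, so recovery tests can
#' compare the fit against the generator. With zero noise the data are the
#' exact curve.
#'
#' @param vmax,km Generating Michaelis-Menten parameters.
#' @param design An [assay_design()].
#' @param variant,substrate Labels carried into the output table.
#' @return A tibble `variant, substrate, substrate_conc_mM, velocity,
#'   replicate` with attribute `ground_truth`.
#' @examples
#' d <- generate_velocity_data(1, 5, assay_design(noise_cv = 0))
#' d$velocity[d$substrate_conc_mM == 5]  # exactly vmax/2
#' @export
generate_velocity_data <- function(vmax, km, design = assay_design(),
                                   variant = "synthetic",
                                   substrate = "synthetic") {
  check_positive_scalar(vmax, "vmax")
  check_positive_scalar(km, "km")
  grid <- rep(design$substrate_grid, each = design$replicates)
  true_v <- mm_velocity(grid, vmax, km)
  noisy <- with_seed(design$seed, {
    eps <- stats::rnorm(length(grid))
    if (!is.null(design$noise_sd)) {
      true_v + design$noise_sd * eps
    } else {
      true_v * (1 + design$noise_cv * eps)
    }
  })
  n_truncated <- sum(noisy < 0)
  out <- tibble(
    variant = variant, substrate = substrate,
    substrate_conc_mM = grid,
    velocity = pmax(noisy, 0),
    replicate = rep(seq_len(design$replicates),
                    times = length(design$substrate_grid))
  )
  attr(out, "ground_truth") <- list(
    vmax = vmax, km = km, enzyme_conc = design$enzyme_conc,
    kcat = vmax / design$enzyme_conc,
    seed = design$seed, n_truncated = n_truncated)
  out
}

#' Generate a synthetic fluorescence plate
#'
#' Forward model of the plate-reader correction: each well's fluorescence is
#' `intensity * (OD - OD_bg) + FP_bg` plus optional additive noise, with
#' per-well ODs drawn uniformly on `od_range`. On noiseless wells,
#' [corrected_fluorescence()] returns the generating intensity exactly.
#'
#' @param intensity True per-OD fluorescence intensity (a.u./OD).
#' @param wells Number of wells (default 96).
#' @param fp_bg,od_bg Background fluorescence and optical density.
#' @param od_range Range of well ODs (default `c(0.5, 1.5)`).
#' @param noise_sd Additive fluorescence noise SD (default 0).
#' @param seed RNG seed.
#' @return A tibble `well, fp, od, fp_bg, od_bg` with attribute
#'   `ground_truth`.
#' @export
generate_plate_data <- function(intensity, wells = 96, fp_bg = 100,
                                od_bg = 0.1, od_range = c(0.5, 1.5),
                                noise_sd = 0, seed = 1) {
  if (wells < 1) abort("`wells` must be >= 1.",
                       class = "phosflux_config_error")
  out <- with_seed(seed, {
    od <- runif(wells, od_range[1], od_range[2])
    fp <- intensity * (od - od_bg) + fp_bg +
      noise_sd * stats::rnorm(wells)
    tibble(well = seq_len(wells), fp = fp, od = od,
           fp_bg = fp_bg, od_bg = od_bg)
  })
  attr(out, "ground_truth") <- list(intensity = intensity, fp_bg = fp_bg,
                                    od_bg = od_bg, noise_sd = noise_sd,
                                    seed = seed)
  out
}
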