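#' Michaelis-Menten initial velocity
#'
#' Evaluates the Michaelis-Menten rate law `v = vmax * s / (Km + s)` for one
#' or more substrate concentrations. The curve is strictly increasing in `s`,
#' bounded above by `vmax`, and reaches `vmax / 2` at `s = Km`.
#'
#' @param substrate_conc Substrate concentration(s), mM. Must be non-negative.
#' @param vmax Maximal velocity (assay units, e.g. µM min^-1). Must be > 0.
#' @param km Michaelis constant, mM. Must be > 0.
#'
#' @return Numeric vector of velocities, same length as `substrate_conc`.
#' @examples
#' mm_velocity(4, vmax = 2, km = 4)  # half-saturation: 1
#' @export
mm_velocity <- function(substrate_conc, vmax, km) {
  check_positive_scalar(vmax, "vmax")
  check_positive_scalar(km, "km")
  if (!is.numeric(substrate_conc) || anyNA(substrate_conc)) {
    abort("`substrate_conc` must be numeric with no missing values.",
          class = "phosflux_invalid_input")
  }
  if (any(substrate_conc < 0)) {
    abort("`substrate_conc` must be non-negative.",
          class = "phosflux_invalid_input")
  }
  vmax * substrate_conc / (km + substrate_conc)
}

#' Turnover number from maximal velocity
#'
#' `kcat = vmax / [E]`, the turnover number given the enzyme (subunit)
#' concentration used in the assay. With `vmax` in µM min^-1 and `enzyme_conc`
#' in µM the result is min^-1.
#'
#' @param vmax Maximal velocity (µM min^-1). Must be >= 0.
#' @param enzyme_conc Enzyme concentration in the assay, µM. Must be > 0.
#'
#' @return Turnover number(s), min^-1.
#' @examples
#' kcat_from_vmax(1, enzyme_conc = 0.1)  # 10 min^-1
#' @export
kcat_from_vmax <- function(vmax, enzyme_conc) {
  if (!is.numeric(enzyme_conc) || anyNA(enzyme_conc) || any(enzyme_conc <= 0)) {
    abort("`enzyme_conc` must be positive.", class = "phosflux_invalid_input")
  }
  if (!is.numeric(vmax) || anyNA(vmax) || any(vmax < 0)) {
    abort("`vmax` must be non-negative.", class = "phosflux_invalid_input")
  }
  vmax / enzyme_conc
}

#' Catalytic efficiency
#'
#' `kcat / Km` in mM^-1 min^-1, the second-order rate constant used throughout
#' as the substrate-preference readout.
#'
#' @param kcat Turnover number, min^-1.
#' @param km Michaelis constant, mM.
#' @return Catalytic efficiency, mM^-1 min^-1.
#' @export
catalytic_efficiency <- function(kcat, km) {
  if (!is.numeric(km) || anyNA(km) || any(km <= 0)) {
    abort("`km` must be positive.", class = "phosflux_invalid_input")
  }
  kcat / km
}

#' Fold change between two catalytic efficiencies
#'
#' Returns all three conventions in one row so a report can pick the one a
#' given claim uses: the plain ratio `value / reference`, the excess
#' `ratio - 1` (the "n-fold increase" reading), and the signed percent change
#' `100 * (ratio - 1)`. The conventions are mutually consistent by
#' construction: `percent_change == 100 * excess` always.
#'
#' @param value Efficiency (or any positive quantity) being compared.
#' @param reference Reference efficiency. Must be > 0.
#' @return A tibble with columns `ratio`, `excess`, `percent_change`.
#' @examples
#' fold_change(126.27, 13.28)  # ratio ~9.51
#' @export
fold_change <- function(value, reference) {
  if (!is.numeric(reference) || anyNA(reference) || any(reference <= 0)) {
    abort("`reference` must be positive.", class = "phosflux_invalid_input")
  }
  r <- value / reference
  tibble(ratio = r, excess = r - 1, percent_change = 100 * (r - 1))
}

#' Background-corrected fluorescence per OD
#'
#' Plate-reader normalisation `(FP - FP_bg) / (OD - OD_bg)`: background
#' fluorescence of a non-expressing strain and background optical density of
#' the medium are subtracted before forming the per-biomass intensity.
#'
#' @param fp Well fluorescence, a.u.
#' @param od Well optical density at 600 nm.
#' @param fp_bg Background fluorescence, a.u.
#' @param od_bg Background optical density.
#' @return Corrected intensity, a.u. per OD. Vectorized over wells.
#' @examples
#' corrected_fluorescence(1000, 1.0, fp_bg = 100, od_bg = 0.1)  # 1000
#' @export
corrected_fluorescence <- function(fp, od, fp_bg = 0, od_bg = 0) {
  if (any(od <= od_bg)) {
    abort("Correction undefined: `od` must exceed `od_bg` in every well.",
          class = "phosflux_undefined_correction")
  }
  (fp - fp_bg) / (od - od_bg)
}

#' Background-correct a plate of readings
#'
#' Data-frame interface to [corrected_fluorescence()]: takes a tidy table of
#' wells with columns `fp`, `od`, `fp_bg`, `od_bg` and appends the corrected
#' per-OD intensity.
#'
#' @param data A data frame with columns `fp`, `od`, `fp_bg`, `od_bg`.
#' @return The input as a tibble with an added `fp_per_od` column.
#' @export
correct_plate <- function(data) {
  require_columns(data, c("fp", "od", "fp_bg", "od_bg"), "plate data")
  as_tibble(data) |>
    mutate(fp_per_od = corrected_fluorescence(.data$fp, .data$od,
                                              .data$fp_bg, .data$od_bg))
}

#' Efficiency unit conversion
#'
#' Converts catalytic efficiencies expressed in µM^-1 s^-1 to the package's
#' canonical mM^-1 min^-1 (and back): 1 µM^-1 s^-1 = 60000 mM^-1 min^-1.
#'
#' @param x Efficiency value(s).
#' @param from,to One of `"mM_min"` or `"uM_s"`.
#' @return Converted value(s).
#' @export
convert_efficiency <- function(x, from = c("uM_s", "mM_min"),
                               to = c("mM_min", "uM_s")) {
  from <- match.arg(from)
  to <- match.arg(to)
  factor <- c(mM_min = 1, uM_s = 60000)
  x * factor[[from]] / factor[[to]]
}
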