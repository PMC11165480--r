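#' @title The GlcNAc biosynthesis pathway model
#'
#' @description
#' An eight-state kinetic model of GlcNAc synthesis in an engineered
#' *E. coli* chassis, in dimensionless (relative) concentration and flux
#' units. States:
#' `x1` glucose, `x2` Glc6P, `x3` Fru6P, `x4` GlcN6P, `x5` fructose,
#' `x6` glucosamine, `x7` GlcNAc6P, `x8` GlcNAc. Twelve reactions connect
#' them: glucose uptake (`v1`, constant or inhibited by phosphosugar
#' pressure), phosphorylation (`v2`), isomerisation Glc6P<->Fru6P (`v3`),
#' amination Fru6P->GlcN6P (`v4`), phosphatase steps on the four
#' phosphosugars (`v5` Glc6P, `v6` Fru6P, `v7` GlcN6P, `v11` GlcNAc6P),
#' GlcNAc6P deacetylase-direction exchange (`v8`), deamination (`v9`),
#' acetylation GlcN6P->GlcNAc6P (`v10`), and fructose re-phosphorylation
#' (`v12`). All non-uptake reactions follow Michaelis-Menten kinetics;
#' the four phosphatase reactions additionally carry a GlcNAc6P-responsive
#' Hill activation prefactor (the biosensor circuit), and uptake is
#' Hill-inhibited by the phosphosugar pool `x2 + x3 + x4 + x7`.
#'
#' @name pathway_model
NULL

state_names <- c("x1", "x2", "x3", "x4", "x5", "x6", "x7", "x8")
rate_names <- paste0("v", 1:12)
phosphatase_reactions <- c(Glc6P = "v5", Fru6P = "v6",
                           GlcN6P = "v7", GlcNAc6P = "v11")

#' Construct and validate pathway parameters
#'
#' @param vmax Named numeric of maximal rates `v1`..`v12` (>= 0).
#' @param km Named numeric of Michaelis constants `Km2`..`Km12` (> 0);
#'   the uptake step `v1` has none.
#' @param p Named numeric of basal phosphatase expression levels for the
#'   regulated reactions `v5`, `v6`, `v7`, `v11` (>= 0).
#' @param hill_n Hill coefficient of the biosensor activation, shared across
#'   the four regulated reactions (in `[0, 4]`).
#' @param ka Half-activation GlcNAc6P level of the biosensor, in `(0, 1]`.
#' @param ki Half-inhibition phosphosugar pool for glucose uptake, `(0, 1]`.
#' @param transport_n Hill coefficient of uptake inhibition (in `[0, 4]`).
#' @param v10_substrate Which state drives the acetylation step `v10`:
#'   `"x4"` (default; mass-consistent with the balance equations, which move
#'   GlcN6P into GlcNAc6P through `v10`) or `"x8"` (the literal printed rate
#'   law).
#' @return A `pathway_params` object.
#' @export
pathway_params <- function(vmax, km, p = c(v5 = 0, v6 = 0, v7 = 0, v11 = 0),
                           hill_n = 1, ka = 0.5, ki = 0.5, transport_n = 1,
                           v10_substrate = c("x4", "x8")) {
  v10_substrate <- match.arg(v10_substrate)
  vmax <- vmax[rate_names]
  km <- km[paste0("Km", 2:12)]
  if (anyNA(vmax) || any(vmax < 0)) {
    abort("`vmax` must supply non-negative v1..v12.",
          class = "phosflux_config_error")
  }
  if (anyNA(km) || any(km <= 0)) {
    abort("`km` must supply positive Km2..Km12.",
          class = "phosflux_config_error")
  }
  p <- p[c("v5", "v6", "v7", "v11")]
  if (anyNA(p) || any(p < 0)) {
    abort("`p` must supply non-negative basal levels for v5, v6, v7, v11.",
          class = "phosflux_config_error")
  }
  if (!is.numeric(hill_n) || !length(hill_n) %in% c(1L, 4L) ||
      anyNA(hill_n) || any(hill_n < 0) || any(hill_n > 4)) {
    abort("`hill_n` must be 1 shared or 4 per-reaction values in [0, 4].",
          class = "phosflux_config_error")
  }
  if (length(hill_n) == 4L) hill_n <- setNames(hill_n, c("v5", "v6", "v7", "v11"))
  if (!is.numeric(transport_n) || length(transport_n) != 1 ||
      is.na(transport_n) || transport_n < 0 || transport_n > 4) {
    abort("`transport_n` must be a single value in [0, 4].",
          class = "phosflux_config_error")
  }
  if (!is.numeric(ka) || ka <= 0 || ka > 1 ||
      !is.numeric(ki) || ki <= 0 || ki > 1) {
    abort("`ka` and `ki` must lie in (0, 1].",
          class = "phosflux_config_error")
  }
  structure(
    list(vmax = vmax, km = km, p = p, hill_n = hill_n, ka = ka, ki = ki,
         transport_n = transport_n, v10_substrate = v10_substrate),
    class = "pathway_params"
  )
}

check_state <- function(state) {
  if (length(state) != 8 || anyNA(state)) {
    abort("state must be 8 finite values x1..x8.",
          class = "phosflux_invalid_state")
  }
  if (any(state < 0)) {
    abort("state components must be non-negative.",
          class = "phosflux_invalid_state")
  }
  setNames(as.numeric(state), state_names)
}

# substrate feeding each MM reaction v2..v12 (v10 mode-dependent)
mm_substrate <- function(state, params) {
  c(v2 = state[["x1"]], v3 = state[["x2"]], v4 = state[["x3"]],
    v5 = state[["x2"]], v6 = state[["x3"]], v7 = state[["x4"]],
    v8 = state[["x7"]], v9 = state[["x4"]],
    v10 = state[[params$v10_substrate]],
    v11 = state[["x7"]], v12 = state[["x5"]])
}

#' Unregulated reaction rates
#'
#' Evaluates the core rate laws at a state: constant uptake `v1 = v1max` and
#' Michaelis-Menten forms `v_i = vmax_i * s / (Km_i + s)` for `v2`..`v12`
#' with the pathway's substrate mapping.
#'
#' @param state Numeric vector `x1`..`x8` (non-negative).
#' @param params A `pathway_params` object.
#' @return Named numeric vector `v1`..`v12`.
#' @export
core_rates <- function(state, params) {
  state <- check_state(state)
  s <- mm_substrate(state, params)
  v <- params$vmax[2:12] * s / (params$km + s)
  c(v1 = unname(params$vmax[["v1"]]), v)
}

# biosensor activation term x7^n / (ka^n + x7^n); 0^0 == 1 in R, so n = 0
# gives 1 / (1 + 1) = 1/2 as the degenerate-exponent convention
hill_activation <- function(x7, n, ka) {
  x7^n / (ka^n + x7^n)
}

#' Regulated reaction rates
#'
#' As [core_rates()], but with the biosensor and phosphosugar-pressure
#' feedbacks active: the four phosphatase reactions are scaled by
#' `p_r + vmax_r * x7^n / (Ka^n + x7^n)` (GlcNAc6P-induced expression on top
#' of basal level `p_r`), and uptake becomes
#' `v1 = v1max * Ki^n_t / (Ki^n_t + (x2 + x3 + x4 + x7)^n_t)`.
#'
#' @inheritParams core_rates
#' @return Named numeric vector `v1`..`v12`.
#' @export
regulated_rates <- function(state, params) {
  state <- check_state(state)
  v <- core_rates(state, params)
  subs <- mm_substrate(state, params)
  for (r in c("v5", "v6", "v7", "v11")) {
    n_r <- if (length(params$hill_n) == 1L) params$hill_n else
      params$hill_n[[r]]
    act <- hill_activation(state[["x7"]], n_r, params$ka)
    s <- subs[[r]]
    kmr <- params$km[[sub("^v", "Km", r)]]
    v[[r]] <- (params$p[[r]] + params$vmax[[r]] * act) * s / (kmr + s)
  }
  pool <- state[["x2"]] + state[["x3"]] + state[["x4"]] + state[["x7"]]
  nt <- params$transport_n
  v[["v1"]] <- params$vmax[["v1"]] * params$ki^nt / (params$ki^nt + pool^nt)
  v
}

#' State derivatives from reaction rates
#'
#' The mass balances of the eight metabolites. Summing all components gives
#' `d(sum x)/dt = v1` exactly: uptake is the model's only source and nothing
#' leaves.
#'
#' @param rates Named numeric `v1`..`v12` (finite).
#' @return Named numeric derivative `x1`..`x8`.
#' @export
mass_balance <- function(rates) {
  v <- setNames(as.numeric(rates[rate_names]), rate_names)
  if (anyNA(v) || any(!is.finite(v))) {
    abort("rates must be finite.", class = "phosflux_invalid_state")
  }
  c(x1 = v[["v1"]] - v[["v2"]] + v[["v5"]],
    x2 = v[["v2"]] - v[["v3"]] - v[["v5"]],
    x3 = v[["v3"]] - v[["v4"]] - v[["v6"]] + v[["v9"]] + v[["v12"]],
    x4 = v[["v4"]] - v[["v7"]] + v[["v8"]] - v[["v9"]] - v[["v10"]],
    x5 = v[["v6"]] - v[["v12"]],
    x6 = v[["v7"]],
    x7 = v[["v10"]] - v[["v8"]] - v[["v11"]],
    x8 = v[["v11"]])
}

#' Simulate the pathway
#'
#' Integrates the mass-balance ODEs with a stiff-capable solver
#' (`deSolve::lsoda`, relative tolerance 1e-8, absolute 1e-10) and returns
#' states and reaction rates on a dense output grid. The grid is
#' quadratically stretched (`t_i = T (i/(n-1))^2`): the model starts empty,
#' so the fast initial transient — uptake collapsing as the phosphosugar
#' pool first crosses `Ki`, which for small `Ki` happens within `t ~ Ki /
#' v1max` — needs resolution that a uniform grid of practical size cannot
#' provide, while the tail is slow and smooth. States are clipped to zero
#' in the output; the solver is considered failed if any component drops
#' below `-1e-9`.
#'
#' @param params A `pathway_params` object.
#' @param initial Initial state (default: all eight states at 0 — the
#'   pathway is fed only by uptake).
#' @param horizon Integration horizon in dimensionless time (default 200).
#' @param n_grid Number of output grid points (default 1001).
#' @param regulated Use the biosensor/pressure-regulated rate laws
#'   (default `TRUE`); `FALSE` integrates the core MM-only model.
#' @param rtol,atol Solver tolerances.
#' @param variant,draw Optional metadata labels carried into the output.
#' @return A `pathway_trajectory`: list with `times`, `states` (matrix
#'   times x 8), `rates` (times x 12), `params` and metadata. Use [tidy()]
#'   for a long tibble and [autoplot()] to plot the state trajectories.
#' @examples
#' p <- example_pathway_params()
#' traj <- simulate_pathway(p, horizon = 50)
#' tidy(traj)
#' @export
simulate_pathway <- function(params, initial = rep(0, 8), horizon = 200,
                             n_grid = 1001, regulated = TRUE,
                             rtol = 1e-8, atol = 1e-10,
                             variant = NA_character_, draw = NA_integer_) {
  if (!inherits(params, "pathway_params")) {
    abort("`params` must be a `pathway_params` object.",
          class = "phosflux_config_error")
  }
  if (!is.numeric(horizon) || horizon <= 0) {
    abort("`horizon` must be positive.", class = "phosflux_config_error")
  }
  initial <- check_state(initial)
  rate_fun <- if (regulated) regulated_rates else core_rates
  deriv <- function(t, y, parms) {
    list(mass_balance(rate_fun(pmax(y, 0), params)))
  }
  times <- horizon * seq(0, 1, length.out = n_grid)^2
  sol <- tryCatch(
    deSolve::lsoda(y = initial, times = times, func = deriv, parms = NULL,
                   rtol = rtol, atol = atol),
    error = function(e) {
      abort(paste0("pathway integration failed: ", conditionMessage(e)),
            class = "phosflux_integration_error")
    }
  )
  if (nrow(sol) < n_grid || anyNA(sol)) {
    abort("pathway integration did not reach the horizon.",
          class = "phosflux_integration_error")
  }
  states <- sol[, state_names, drop = FALSE]
  if (min(states) < -1e-9) {
    abort(sprintf("state fell below tolerance (min %.3g): integration unreliable.",
                  min(states)), class = "phosflux_integration_error")
  }
  states <- pmax(states, 0)
  rates <- t(apply(states, 1, rate_fun, params = params))
  colnames(rates) <- rate_names
  structure(
    list(times = times, states = states, rates = rates, params = params,
         regulated = regulated, variant = variant, draw = draw),
    class = "pathway_trajectory"
  )
}

#' @export
print.pathway_trajectory <- function(x, ...) {
  cat(sprintf(
    "pathway trajectory: T = %g, %d grid points%s\n  final state: %s\n",
    max(x$times), length(x$times),
    if (!is.na(x$variant)) paste0(", variant ", x$variant) else "",
    paste(sprintf("%s=%.4g", state_names, x$states[nrow(x$states), ]),
          collapse = " ")))
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param x A `pathway_trajectory`.
#' @param rates Include reaction rates as well as states (default `FALSE`).
#' @param ... Unused.
#' @return A tibble `variant, draw, time, series, value` where `series` is a
#'   state (`x1`..`x8`) or, with `rates = TRUE`, also a reaction (`v1`..`v12`).
#' @export
tidy.pathway_trajectory <- function(x, rates = FALSE, ...) {
  wide <- as_tibble(as.data.frame(x$states)) |>
    mutate(time = x$times, variant = x$variant, draw = x$draw)
  if (rates) {
    wide <- dplyr::bind_cols(wide, as_tibble(as.data.frame(x$rates)))
  }
  wide |>
    tidyr::pivot_longer(cols = -c("time", "variant", "draw"),
                        names_to = "series", values_to = "value") |>
    select("variant", "draw", "time", "series", "value")
}

#' @export
#' @rdname tidy.pathway_trajectory
#' @param object A `pathway_trajectory`.
autoplot.pathway_trajectory <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$value,
                                 colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (relative units)",
                  y = "relative concentration", colour = "state") +
    ggplot2::theme_minimal()
}

#' Source-balance check of a trajectory
#'
#' Uptake is the model's only source, so the total metabolite pool must obey
#' `sum(x(T)) - sum(x(0)) = integral of v1 dt`. This recomputes both sides —
#' the right-hand side by composite Simpson quadrature on the stored `v1`
#' series — and returns the relative gap.
#'
#' @param trajectory A `pathway_trajectory`.
#' @return Relative error `|sum x(T) - sum x(0) - ∫v1| / ∫v1`.
#' @export
flux_balance_error <- function(trajectory) {
  gained <- sum(trajectory$states[nrow(trajectory$states), ]) -
    sum(trajectory$states[1, ])
  uptake <- integrate_series(trajectory$times, trajectory$rates[, "v1"])
  abs(gained - uptake) / abs(uptake)
}

#' Per-trajectory summary statistics
#'
#' The quantities used to compare phosphatase variants: final GlcNAc
#' (`final_product = x8(T)`), depth of Glc6P depletion (`min_glc6p`, the
#' minimum of `x2` over the second half of the horizon — the pathway starts
#' empty, so the raw all-time minimum would trivially be the initial zero;
#' the second-half minimum measures the quasi-steady depletion level
#' instead), final fructose and glucosamine pools (accumulation
#' indicators), and the time-average and maximum of the GlcNAc6P signal
#' `x7`.
#'
#' @param trajectory A `pathway_trajectory`.
#' @return A one-row tibble.
#' @export
summarize_trajectory <- function(trajectory) {
  st <- trajectory$states
  tt <- trajectory$times
  x7 <- st[, "x7"]
  second_half <- tt >= (min(tt) + max(tt)) / 2
  tibble(
    variant = trajectory$variant,
    draw = trajectory$draw,
    final_product = st[nrow(st), "x8"],
    min_glc6p = min(st[second_half, "x2"]),
    final_fructose = st[nrow(st), "x5"],
    final_glucosamine = st[nrow(st), "x6"],
    mean_glcnac6p = integrate_series(tt, x7) / (max(tt) - min(tt)),
    max_glcnac6p = max(x7)
  )
}

#' A fixed example parameter set
#'
#' A deterministic mid-range parameter set (all sampled quantities at the
#' midpoints of their sampling ranges, wild-type phosphatase ratios) used in
#' examples and smoke tests.
#'
#' @return A `pathway_params` object.
#' @export
example_pathway_params <- function() {
  base <- list(
    vmax = c(v1 = 0.5, v2 = 0.8, v3 = 0.8, v4 = 0.8, v8 = 0.8, v9 = 0.8,
             v10 = 0.8, v12 = 0.8),
    km = c(Km2 = 1.25, Km3 = 1.25, Km4 = 1.25, Km8 = 1.25, Km9 = 1.25,
           Km10 = 1.25, Km12 = 1.25),
    km_wt_glc6p = 1.25, hill_n = 2, ka = 0.5, ki = 0.5, transport_n = 2
  )
  build_variant_params(default_ratio_table(), base, "WT")
}
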