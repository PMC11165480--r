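#' Fit the Michaelis-Menten equation to initial-velocity data
#'
#' Nonlinear least squares fit of `v = vmax * s / (Km + s)` to an
#' initial-velocity dataset, as used for the 1-80 mM substrate-gradient
#' phosphatase assays. Starting values follow the standard heuristic:
#' `vmax0` is the largest observed velocity and `Km0` the substrate
#' concentration whose mean velocity lies nearest `vmax0 / 2`. Residuals are
#' unweighted by default; `weighting = "inv_v2"` applies 1/v^2 weights
#' (relative-error weighting), using the fitted-free observed velocities.
#'
#' @param data A data frame with columns `substrate_conc_mM` and `velocity`
#'   (a `replicate` column is allowed and ignored by the fit).
#' @param enzyme_conc Optional enzyme concentration (µM). When given, `kcat`
#'   (min^-1) and catalytic efficiency `kcat/Km` (mM^-1 min^-1) are derived.
#' @param weighting `"none"` (default) or `"inv_v2"`.
#'
#' @return An object of class `mm_fit`. Use [tidy()] for the coefficient
#'   table, [glance()] for fit diagnostics, [autoplot()] for the fitted curve.
#' @examples
#' d <- generate_velocity_data(vmax = 1, km = 5, assay_design(noise_cv = 0))
#' fit <- fit_michaelis_menten(d)
#' tidy(fit)
#' @export
fit_michaelis_menten <- function(data, enzyme_conc = NULL,
                                 weighting = c("none", "inv_v2")) {
  weighting <- match.arg(weighting)
  require_columns(data, c("substrate_conc_mM", "velocity"), "velocity data")
  s <- data$substrate_conc_mM
  v <- data$velocity
  if (anyNA(s) || anyNA(v) || any(!is.finite(v))) {
    abort("velocities and concentrations must be finite.",
          class = "phosflux_data_error")
  }
  if (any(s < 0)) {
    abort("substrate concentrations must be non-negative.",
          class = "phosflux_data_error")
  }
  if (length(unique(s)) < 3L) {
    abort("at least 3 distinct substrate concentrations are required to fit.",
          class = "phosflux_insufficient_design")
  }
  if (all(v <= 0)) {
    abort("all velocities are zero or negative; the curve is unidentifiable.",
          class = "phosflux_fit_failure")
  }

  vmax0 <- max(v)
  mean_v <- tapply(v, s, mean)
  km0 <- as.numeric(names(mean_v))[which.min(abs(mean_v - vmax0 / 2))]
  km0 <- max(km0, min(s[s > 0], na.rm = TRUE) / 10, 1e-6)

  w <- if (weighting == "inv_v2") 1 / pmax(v, 1e-8)^2 else rep(1, length(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * s / (km + s),
      data = list(v = v, s = s),
      start = list(vmax = vmax0, km = km0),
      weights = w,
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-14, ptol = 1e-14, maxiter = 200)
    ),
    error = function(e) {
      abort(paste0("Michaelis-Menten fit failed: ", conditionMessage(e)),
            class = "phosflux_fit_failure")
    }
  )

  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  kcat <- if (!is.null(enzyme_conc)) kcat_from_vmax(est[["vmax"]], enzyme_conc)
  structure(
    list(
      vmax = est[["vmax"]],
      km = est[["km"]],
      vmax_se = unname(se[["vmax"]]),
      km_se = unname(se[["km"]]),
      enzyme_conc = enzyme_conc,
      kcat = kcat,
      efficiency = if (!is.null(kcat)) kcat / est[["km"]],
      rss = sum(stats::resid(fit)^2),
      n_obs = length(v),
      n_conc = length(unique(s)),
      weighting = weighting,
      converged = fit$convInfo$isConv %||% TRUE,
      fit = fit,
      data = tibble(substrate_conc_mM = s, velocity = v)
    ),
    class = "mm_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (", x$n_obs, " obs, ",
      x$n_conc, " concentrations)\n", sep = "")
  cat(sprintf("  vmax = %.6g (se %.3g)\n  Km   = %.6g mM (se %.3g)\n",
              x$vmax, x$vmax_se, x$km, x$km_se))
  if (!is.null(x$kcat)) {
    cat(sprintf("  kcat = %.6g min^-1, kcat/Km = %.6g mM^-1 min^-1\n",
                x$kcat, x$efficiency))
  }
  invisible(x)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.mm_fit <- function(x, ...) {
  out <- tibble(
    term = c("vmax", "km"),
    estimate = c(x$vmax, x$km),
    std.error = c(x$vmax_se, x$km_se)
  )
  if (!is.null(x$kcat)) {
    out <- bind_rows(out, tibble(
      term = c("kcat", "efficiency"),
      estimate = c(x$kcat, x$efficiency),
      std.error = NA_real_
    ))
  }
  out
}

#' One-row fit diagnostics
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `rss`, `sigma`, `n_obs`, `n_conc`, `converged`.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(
    rss = x$rss,
    sigma = sqrt(x$rss / max(x$n_obs - 2, 1)),
    n_obs = x$n_obs,
    n_conc = x$n_conc,
    converged = x$converged
  )
}

#' Plot an MM fit: observed velocities and the fitted curve
#'
#' @param object An `mm_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(
    substrate_conc_mM = seq(0, max(object$data$substrate_conc_mM),
                            length.out = 200)
  ) |>
    mutate(velocity = mm_velocity(.data$substrate_conc_mM,
                                  object$vmax, object$km))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$substrate_conc_mM, .data$velocity)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(x = "substrate (mM)", y = "initial velocity",
                  title = sprintf("vmax = %.3g, Km = %.3g mM",
                                  object$vmax, object$km)) +
    ggplot2::theme_minimal()
}

#' Fit every (variant, substrate) series in a tidy velocity table
#'
#' Groups a tidy velocity table by `variant` and `substrate` and fits each
#' series with [fit_michaelis_menten()], collecting estimates and diagnostics
#' into one row per series. Failed fits are reported in the `status` column
#' rather than aborting the whole table.
#'
#' @param data A data frame with columns `variant`, `substrate`,
#'   `substrate_conc_mM`, `velocity`.
#' @param enzyme_conc Optional enzyme concentration (µM), scalar or a data
#'   frame with columns `variant`, `substrate`, `enzyme_conc_uM`.
#' @inheritParams fit_michaelis_menten
#' @return A tibble with one row per (variant, substrate): estimates,
#'   standard errors, `rss`, `status` (`"ok"` or the error message).
#' @export
fit_kinetics <- function(data, enzyme_conc = NULL,
                         weighting = c("none", "inv_v2")) {
  weighting <- match.arg(weighting)
  require_columns(data, c("variant", "substrate", "substrate_conc_mM",
                          "velocity"), "velocity data")
  ec_tbl <- NULL
  if (is.data.frame(enzyme_conc)) {
    require_columns(enzyme_conc, c("variant", "substrate", "enzyme_conc_uM"),
                    "enzyme concentration table")
    ec_tbl <- enzyme_conc
  }
  as_tibble(data) |>
    group_by(.data$variant, .data$substrate) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(row = purrr::pmap(
      list(.data$variant, .data$substrate, .data$data),
      function(variant, substrate, d) {
        ec <- if (!is.null(ec_tbl)) {
          hit <- ec_tbl$enzyme_conc_uM[ec_tbl$variant == variant &
                                         ec_tbl$substrate == substrate]
          if (length(hit)) hit[[1]] else NULL
        } else {
          enzyme_conc
        }
        res <- tryCatch(
          fit_michaelis_menten(d, enzyme_conc = ec, weighting = weighting),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          tibble(vmax = NA_real_, km = NA_real_, vmax_se = NA_real_,
                 km_se = NA_real_, kcat = NA_real_, efficiency = NA_real_,
                 rss = NA_real_, status = conditionMessage(res))
        } else {
          tibble(vmax = res$vmax, km = res$km, vmax_se = res$vmax_se,
                 km_se = res$km_se,
                 kcat = res$kcat %||% NA_real_,
                 efficiency = res$efficiency %||% NA_real_,
                 rss = res$rss, status = "ok")
        }
      })) |>
    select(-"data") |>
    tidyr::unnest("row")
}
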