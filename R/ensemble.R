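#' Monte-Carlo sampling specification
#'
#' Defines the randomized parameter scheme for ensemble simulation. Defaults
#' are the study conditions: non-phosphatase Michaelis constants and the
#' wild-type Glc6P Km uniform on `[0.5, 2]`; non-phosphatase maxima uniform
#' on `[0.6, 1]`; uptake `v1max` and the wild-type Glc6P phosphatase vmax
#' fixed at 0.5; Hill coefficients uniform on `[0, 4]` (biosensor exponents
#' truncated below at 1e-6 to avoid the degenerate `0^0` case); `Ka` and
#' `Ki` uniform on `[0.01, 1]` (the lower end pulled off 0 to keep the Hill
#' terms well-conditioned).
#'
#' @param n_draws Number of parameter draws (default 200).
#' @param seed Base RNG seed. Each draw derives its own sub-seed from
#'   `(seed, draw)`, so draw `i` is identical regardless of `n_draws` and is
#'   shared across variants (paired design).
#' @param km_nonphos_range,km_wt_glc6p_range,vmax_nonphos_range,
#'   hill_n_range,ka_range,ki_range Sampling intervals.
#' @param vmax_glc6p_wt,v1max Fixed anchor constants.
#' @param shared_hill One biosensor Hill coefficient shared by the four
#'   regulated reactions (default `TRUE`); `FALSE` draws one per reaction.
#' @return A `sampling_spec` object (a validated list).
#' @export
sampling_spec <- function(n_draws = 200, seed = 1,
                          km_nonphos_range = c(0.5, 2),
                          km_wt_glc6p_range = c(0.5, 2),
                          vmax_nonphos_range = c(0.6, 1),
                          vmax_glc6p_wt = 0.5, v1max = 0.5,
                          hill_n_range = c(0, 4),
                          ka_range = c(0.01, 1),
                          ki_range = c(0.01, 1),
                          shared_hill = TRUE) {
  ranges <- list(km_nonphos_range = km_nonphos_range,
                 km_wt_glc6p_range = km_wt_glc6p_range,
                 vmax_nonphos_range = vmax_nonphos_range,
                 hill_n_range = hill_n_range,
                 ka_range = ka_range, ki_range = ki_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2 || anyNA(r) || r[1] > r[2]) {
      abort(sprintf("`%s` must be a non-empty interval c(lo, hi).", nm),
            class = "phosflux_config_error")
    }
  }
  if (!is.numeric(n_draws) || n_draws < 1) {
    abort("`n_draws` must be >= 1.", class = "phosflux_config_error")
  }
  structure(
    c(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
           vmax_glc6p_wt = vmax_glc6p_wt, v1max = v1max,
           shared_hill = isTRUE(shared_hill)),
      ranges),
    class = "sampling_spec")
}

nonphos_reactions <- c("v2", "v3", "v4", "v8", "v9", "v10", "v12")

#' Draw one base parameter set
#'
#' Samples the non-variant-specific parameters for one draw index: the seven
#' non-phosphatase Km and vmax values, the wild-type Glc6P Km, the Hill
#' coefficients, `Ka` and `Ki`. The same `(spec$seed, draw)` pair always
#' yields the same base draw, independent of how many draws the ensemble
#' runs, so every variant of a draw sees the identical base parameters.
#'
#' @param spec A `sampling_spec`.
#' @param draw Draw index (1-based).
#' @return A base-draw list consumable by [build_variant_params()].
#' @export
sample_parameters <- function(spec, draw) {
  if (!inherits(spec, "sampling_spec")) {
    abort("`spec` must be a `sampling_spec`.", class = "phosflux_config_error")
  }
  with_seed(draw_seed(spec$seed, draw), {
    km <- setNames(runif(7, spec$km_nonphos_range[1],
                         spec$km_nonphos_range[2]),
                   sub("^v", "Km", nonphos_reactions))
    vmax <- setNames(runif(7, spec$vmax_nonphos_range[1],
                           spec$vmax_nonphos_range[2]),
                     nonphos_reactions)
    km_wt <- runif(1, spec$km_wt_glc6p_range[1], spec$km_wt_glc6p_range[2])
    n_hill <- pmax(runif(if (spec$shared_hill) 1 else 4,
                         spec$hill_n_range[1], spec$hill_n_range[2]), 1e-6)
    if (!spec$shared_hill) names(n_hill) <- c("v5", "v6", "v7", "v11")
    n_t <- runif(1, spec$hill_n_range[1], spec$hill_n_range[2])
    ka <- runif(1, spec$ka_range[1], spec$ka_range[2])
    ki <- runif(1, spec$ki_range[1], spec$ki_range[2])
    list(
      vmax = c(c(v1 = spec$v1max), vmax),
      km = km,
      km_wt_glc6p = km_wt,
      hill_n = n_hill,
      ka = ka, ki = ki,
      transport_n = n_t,
      draw = as.integer(draw)
    )
  })
}

#' Run a seeded variant-comparison ensemble
#'
#' For each parameter draw and each phosphatase variant, builds the variant's
#' pathway parameters ([build_variant_params()]), simulates
#' ([simulate_pathway()]) and summarizes ([summarize_trajectory()]). Base
#' draws are shared across variants within a draw, so comparisons are
#' paired. Individual integration failures are recorded per draw rather
#' than aborting; the run errors only if more than `max_fail_frac` of all
#' (draw, variant) simulations fail.
#'
#' @param spec A `sampling_spec`.
#' @param variants Character vector of variant labels
#'   (default `c("WT","M1","M2","M3")`).
#' @param ratios Ratio table (default [default_ratio_table()]).
#' @param horizon,n_grid,initial,v10_substrate,basal_mult Passed through to
#'   the model; see [simulate_pathway()] and [build_variant_params()].
#' @param keep_trajectories Retain full trajectories (memory-heavy;
#'   default `FALSE`).
#' @param max_fail_frac Maximum tolerated fraction of failed integrations
#'   (default 0.1).
#' @return A `pathway_ensemble`: list with the spec, a `summaries` tibble
#'   (`variant, draw, final_product, min_glc6p, final_fructose,
#'   final_glucosamine, mean_glcnac6p, max_glcnac6p, status`), and optional
#'   trajectories. [tidy()] returns the summaries; [glance()] one-row run
#'   metadata; [autoplot()] a per-variant distribution plot.
#' @examples
#' \donttest{
#' ens <- run_ensemble(sampling_spec(n_draws = 5, seed = 1))
#' tidy(ens)
#' }
#' @export
run_ensemble <- function(spec, variants = c("WT", "M1", "M2", "M3"),
                         ratios = default_ratio_table(), horizon = 200,
                         n_grid = 1001, initial = rep(0, 8),
                         v10_substrate = c("x4", "x8"),
                         basal_mult = 1, keep_trajectories = FALSE,
                         max_fail_frac = 0.1) {
  v10_substrate <- match.arg(v10_substrate)
  for (v in variants) {
    if (!v %in% ratios$variant ||
        length(setdiff(names(phosphatase_reactions),
                       ratios$substrate[ratios$variant == v]))) {
      abort(sprintf(
        "variant '%s' is not fully resolvable in the ratio table.", v),
        class = "phosflux_config_error")
    }
  }
  rows <- vector("list", spec$n_draws * length(variants))
  trajs <- if (keep_trajectories) vector("list", length(rows))
  k <- 0L
  for (draw in seq_len(spec$n_draws)) {
    base <- sample_parameters(spec, draw)
    for (v in variants) {
      k <- k + 1L
      res <- tryCatch({
        params <- build_variant_params(ratios, base, v,
                                       vmax_scale = spec$vmax_glc6p_wt,
                                       basal_mult = basal_mult,
                                       v10_substrate = v10_substrate)
        traj <- simulate_pathway(params, initial = initial, horizon = horizon,
                                 n_grid = n_grid, variant = v, draw = draw)
        list(summary = summarize_trajectory(traj), traj = traj)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[k]] <- tibble(
          variant = v, draw = draw, final_product = NA_real_,
          min_glc6p = NA_real_, final_fructose = NA_real_,
          final_glucosamine = NA_real_, mean_glcnac6p = NA_real_,
          max_glcnac6p = NA_real_, status = conditionMessage(res))
      } else {
        rows[[k]] <- mutate(res$summary, status = "ok")
        if (keep_trajectories) trajs[[k]] <- res$traj
      }
    }
  }
  summaries <- bind_rows(rows)
  fail_frac <- mean(summaries$status != "ok")
  if (fail_frac > max_fail_frac) {
    abort(sprintf("%.0f%% of integrations failed (limit %.0f%%).",
                  100 * fail_frac, 100 * max_fail_frac),
          class = "phosflux_ensemble_quality_error")
  }
  structure(
    list(spec = spec, variants = variants, ratios = ratios,
         horizon = horizon, v10_substrate = v10_substrate,
         basal_mult = basal_mult, summaries = summaries,
         trajectories = if (keep_trajectories) trajs),
    class = "pathway_ensemble")
}

#' @export
print.pathway_ensemble <- function(x, ...) {
  cat(sprintf(
    "pathway ensemble: %d draws x %d variants (seed %d), %d/%d ok\n",
    x$spec$n_draws, length(x$variants), x$spec$seed,
    sum(x$summaries$status == "ok"), nrow(x$summaries)))
  print(compare_variants(x))
  invisible(x)
}

#' @param x,object A `pathway_ensemble`.
#' @param ... Unused.
#' @rdname run_ensemble
#' @export
tidy.pathway_ensemble <- function(x, ...) x$summaries

#' @rdname run_ensemble
#' @export
glance.pathway_ensemble <- function(x, ...) {
  tibble(n_draws = x$spec$n_draws, seed = x$spec$seed,
         n_variants = length(x$variants), horizon = x$horizon,
         v10_substrate = x$v10_substrate,
         n_failed = sum(x$summaries$status != "ok"))
}

#' @rdname run_ensemble
#' @export
autoplot.pathway_ensemble <- function(object, ...) {
  object$summaries |>
    filter(.data$status == "ok") |>
    mutate(variant = factor(.data$variant, levels = object$variants)) |>
    ggplot2::ggplot(ggplot2::aes(.data$variant, .data$final_product)) +
    ggplot2::geom_boxplot(fill = "#d1e5f0") +
    ggplot2::labs(x = NULL, y = "final GlcNAc (relative units)") +
    ggplot2::theme_minimal()
}

#' Paired variant comparison
#'
#' Summarizes an ensemble against a reference variant, pairing statistics on
#' the shared base draws: per-variant medians of the trajectory summaries,
#' the paired median difference in final GlcNAc, the per-draw win fraction
#' (fraction of draws where the variant's final GlcNAc exceeds the
#' reference's; ties count 1/2), and accumulation flags marking whether the
#' median final fructose / glucosamine pools stay below
#' `accumulation_threshold` times the variant's median final GlcNAc.
#'
#' @param ensemble A `pathway_ensemble`.
#' @param reference Reference variant label (default `"WT"`).
#' @param accumulation_threshold Fraction of final product below which a
#'   byproduct pool counts as non-accumulating (default 0.05).
#' @return A tibble with one row per variant.
#' @export
compare_variants <- function(ensemble, reference = "WT",
                             accumulation_threshold = 0.05) {
  s <- ensemble$summaries |> filter(.data$status == "ok")
  if (!reference %in% s$variant) {
    abort(sprintf("reference variant '%s' absent from ensemble.", reference),
          class = "phosflux_config_error")
  }
  ref <- s |>
    filter(.data$variant == reference) |>
    select("draw", ref_final = "final_product")
  s |>
    left_join(ref, by = "draw") |>
    group_by(.data$variant) |>
    summarise(
      n_ok = dplyr::n(),
      median_final_product = median(.data$final_product),
      median_min_glc6p = median(.data$min_glc6p),
      median_final_fructose = median(.data$final_fructose),
      median_final_glucosamine = median(.data$final_glucosamine),
      median_mean_glcnac6p = median(.data$mean_glcnac6p),
      median_max_glcnac6p = median(.data$max_glcnac6p),
      median_paired_diff = median(.data$final_product - .data$ref_final),
      win_fraction = mean(
        (.data$final_product > .data$ref_final) +
          0.5 * (.data$final_product == .data$ref_final)),
      .groups = "drop") |>
    mutate(
      reference = reference,
      fructose_accumulates =
        .data$median_final_fructose >
          accumulation_threshold * .data$median_final_product,
      glucosamine_accumulates =
        .data$median_final_glucosamine >
          accumulation_threshold * .data$median_final_product
    ) |>
    mutate(variant = factor(.data$variant, levels = ensemble$variants)) |>
    arrange(.data$variant) |>
    mutate(variant = as.character(.data$variant))
}
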