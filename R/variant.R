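#' Variant ratio table from a kcat/Km panel
#'
#' Maps a measured efficiency panel onto the dimensionless pathway model.
#' The wild-type Glc6P phosphatase reaction anchors the scale, so each
#' variant/substrate pair gets `vmax_ratio = kcat_km(variant, substrate) /
#' kcat_km(WT, Glc6P)`; the entire measured preference is carried by vmax
#' and `km_ratio` is fixed at 1 (kcat/Km is the only measured quantity, so
#' the vmax/Km split is not identifiable — this table is the single place
#' to swap in a different split). Unmeasured pairs are dropped unless an
#' imputation policy names a donor variant.
#'
#' @param panel A `kinetic_panel` (default: the packaged BT4131 panel).
#' @param reference_variant Variant anchoring the scale (default `"WT"`).
#' @param reference_substrate Substrate anchoring the scale
#'   (default `"Glc6P"`).
#' @param impute Optional named character vector of donor variants for
#'   missing entries, e.g. `c(M4 = "M3")`: M4's unmeasured substrates take
#'   M3's ratios, flagged `provenance = "imputed"`.
#' @return A tibble `variant, substrate, vmax_ratio, km_ratio, provenance`.
#'   The reference pair has both ratios exactly 1.
#' @export
default_ratio_table <- function(panel = bt4131_panel(),
                                reference_variant = "WT",
                                reference_substrate = "Glc6P",
                                impute = NULL) {
  panel <- if (inherits(panel, "kinetic_panel")) panel else kinetic_panel(panel)
  anchor <- panel$kcat_km[panel$variant == reference_variant &
                            panel$substrate == reference_substrate]
  if (length(anchor) != 1 || is.na(anchor)) {
    abort(sprintf("panel lacks a measured (%s, %s) anchor entry.",
                  reference_variant, reference_substrate),
          class = "phosflux_data_error")
  }
  tbl <- panel |>
    filter(.data$measured) |>
    mutate(vmax_ratio = .data$kcat_km / anchor, km_ratio = 1,
           provenance = "measured") |>
    select("variant", "substrate", "vmax_ratio", "km_ratio", "provenance")
  if (!is.null(impute)) {
    extra <- purrr::imap(impute, function(donor, target) {
      have <- tbl$substrate[tbl$variant == target]
      tbl |>
        filter(.data$variant == donor, !(.data$substrate %in% have)) |>
        mutate(variant = target, provenance = "imputed")
    })
    tbl <- bind_rows(tbl, bind_rows(extra))
  }
  arrange(tbl, .data$variant, .data$substrate)
}

#' Build pathway parameters for a phosphatase variant
#'
#' Combines a base parameter draw (non-phosphatase kinetics, the wild-type
#' Glc6P Km, and the regulation constants) with a variant's ratio table to
#' produce a full `pathway_params`. Phosphatase maxima are
#' `vmax_scale * vmax_ratio(variant, substrate)` with the wild-type Glc6P
#' reaction fixed at `vmax_scale = 0.5`; phosphatase Michaelis constants are
#' `km_wt_glc6p * km_ratio`. The basal expression level of each regulated
#' reaction is `p_r = basal_mult * vmax_r` (basal expression equal to the
#' variant-scaled maximum by default, so full biosensor induction doubles
#' the rate ceiling).
#'
#' @param ratios A ratio table as from [default_ratio_table()].
#' @param base A list with elements `vmax` (named, `v1` plus the
#'   non-phosphatase reactions `v2,v3,v4,v8,v9,v10,v12`), `km` (named
#'   `Km2,Km3,Km4,Km8,Km9,Km10,Km12`), `km_wt_glc6p`, `hill_n`, `ka`, `ki`,
#'   `transport_n` — the shape produced by [sample_parameters()].
#' @param variant Variant label to build.
#' @param vmax_scale Anchor vmax of the wild-type Glc6P reaction
#'   (default 0.5).
#' @param basal_mult Basal expression as a multiple of each regulated
#'   reaction's vmax (default 1).
#' @param v10_substrate Passed to [pathway_params()].
#' @return A `pathway_params` object.
#' @export
build_variant_params <- function(ratios, base, variant, vmax_scale = 0.5,
                                 basal_mult = 1,
                                 v10_substrate = c("x4", "x8")) {
  v10_substrate <- match.arg(v10_substrate)
  substrates <- names(phosphatase_reactions)
  rows <- ratios[ratios$variant == variant, , drop = FALSE]
  missing <- setdiff(substrates, rows$substrate)
  if (length(missing)) {
    abort(sprintf(
      "no ratio for pair(s): %s; supply an imputation policy or a complete table.",
      paste(paste0("(", variant, ", ", missing, ")"), collapse = ", ")),
      class = "phosflux_config_error")
  }
  vr <- setNames(rows$vmax_ratio[match(substrates, rows$substrate)],
                 phosphatase_reactions)
  kr <- setNames(rows$km_ratio[match(substrates, rows$substrate)],
                 phosphatase_reactions)
  phos_vmax <- vmax_scale * vr
  phos_km <- setNames(base$km_wt_glc6p * kr,
                      sub("^v", "Km", phosphatase_reactions))
  vmax <- c(base$vmax, phos_vmax)[rate_names]
  km <- c(base$km, phos_km)[paste0("Km", 2:12)]
  pathway_params(
    vmax = vmax, km = km,
    p = basal_mult * phos_vmax,
    hill_n = base$hill_n, ka = base$ka, ki = base$ki,
    transport_n = base$transport_n,
    v10_substrate = v10_substrate
  )
}
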