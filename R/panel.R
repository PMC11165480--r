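#' Validate a kcat/Km panel table
#'
#' A kinetic panel is a tidy table of catalytic efficiencies (kcat/Km,
#' mM^-1 min^-1) for enzyme variants across substrates, with an SD where
#' replicates were measured and a `measured` flag for substrate/variant pairs
#' that were not assayed. Measured entries must carry positive efficiencies;
#' unmeasured entries carry no value.
#'
#' @param data A data frame with columns `variant`, `substrate`, `kcat_km`,
#'   `sd`, `measured`.
#' @return The validated panel as a tibble of class `kinetic_panel`.
#' @export
kinetic_panel <- function(data) {
  require_columns(data, c("variant", "substrate", "kcat_km", "sd", "measured"),
                  "panel")
  data <- as_tibble(data)
  if (!is.logical(data$measured) || anyNA(data$measured)) {
    abort("`measured` must be TRUE/FALSE with no missing values.",
          class = "phosflux_data_error")
  }
  bad <- data$measured & (is.na(data$kcat_km) | data$kcat_km <= 0)
  if (any(bad)) {
    abort(sprintf(
      "measured entries must have positive kcat/Km; offending pair(s): %s.",
      paste(paste0("(", data$variant[bad], ", ", data$substrate[bad], ")"),
            collapse = ", ")), class = "phosflux_data_error")
  }
  if (anyDuplicated(data[c("variant", "substrate")])) {
    abort("duplicate (variant, substrate) pairs in panel.",
          class = "phosflux_data_error")
  }
  class(data) <- c("kinetic_panel", class(data))
  data
}

#' The measured BT4131 variant panel
#'
#' The packaged kcat/Km panel (mM^-1 min^-1, mean ± SD over three biological
#' replicates) for wild-type phosphatase BT4131 and its engineered variants
#' M1 (L129Q), M2 (L129Q/G172L), M3 (I49Q/L129Q) and M4 (I49Q/L129Q/G172L)
#' across the four phosphosugar substrates Glc6P, Fru6P, GlcN6P and GlcNAc6P.
#' M4 was not assayed on Fru6P or GlcN6P; those rows carry `measured = FALSE`.
#'
#' @return A `kinetic_panel` tibble with 20 rows.
#' @examples
#' bt4131_panel()
#' @export
bt4131_panel <- function() {
  path <- system.file("extdata", "bt4131_panel.csv", package = "phosflux",
                      mustWork = TRUE)
  read_panel_csv(path)
}

#' Read / write a panel CSV
#'
#' Panel CSVs carry columns `variant,substrate,kcat_km,sd,measured`;
#' unmeasured pairs leave `kcat_km` and `sd` empty.
#'
#' @param path File path.
#' @return `read_panel_csv()` returns a validated `kinetic_panel`.
#' @export
read_panel_csv <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      variant = readr::col_character(),
      substrate = readr::col_character(),
      kcat_km = readr::col_double(),
      sd = readr::col_double(),
      measured = readr::col_logical()
    ))
  kinetic_panel(data)
}

#' @param panel A `kinetic_panel`.
#' @rdname read_panel_csv
#' @export
write_panel_csv <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' Substrate-preference comparison report
#'
#' Compares every measured (variant, substrate) efficiency against the same
#' substrate in a reference variant, emitting all three fold-change
#' conventions (`ratio`, `excess = ratio - 1`, `percent_change`) plus
#' display-rounded versions (fold values to 1 decimal, percents to 1
#' decimal, round-half-up). Unmeasured pairs are kept in the output with
#' `measured = FALSE` and missing statistics — they are flagged, never
#' silently imputed.
#'
#' @param panel A `kinetic_panel` (or data frame coercible to one).
#' @param reference Reference variant label (default `"WT"`).
#' @return A tibble with one row per (variant, substrate), columns
#'   `variant`, `substrate`, `reference`, `kcat_km`, `ref_kcat_km`,
#'   `ratio`, `excess`, `percent_change`, `ratio_display`, `excess_display`,
#'   `percent_display`, `measured`.
#' @examples
#' preference_report(bt4131_panel())
#' @export
preference_report <- function(panel, reference = "WT") {
  panel <- if (inherits(panel, "kinetic_panel")) panel else kinetic_panel(panel)
  ref <- panel |>
    filter(.data$variant == reference) |>
    select(substrate = "substrate", ref_kcat_km = "kcat_km",
           ref_measured = "measured")
  if (nrow(ref) == 0) {
    abort(sprintf("reference variant '%s' not present in panel.", reference),
          class = "phosflux_data_error")
  }
  out <- panel |>
    left_join(ref, by = "substrate")
  need_ref <- out$measured & (is.na(out$ref_measured) | !out$ref_measured)
  if (any(need_ref)) {
    abort(sprintf(
      "reference entry missing for pair(s): %s.",
      paste(paste0("(", reference, ", ", out$substrate[need_ref], ")"),
            collapse = ", ")), class = "phosflux_data_error")
  }
  out |>
    mutate(
      reference = reference,
      ratio = ifelse(.data$measured, .data$kcat_km / .data$ref_kcat_km,
                     NA_real_),
      excess = .data$ratio - 1,
      percent_change = 100 * .data$excess,
      ratio_display = round_half_up(.data$ratio, 1),
      excess_display = round_half_up(.data$excess, 1),
      percent_display = round_half_up(.data$percent_change, 1)
    ) |>
    select("variant", "substrate", "reference", "kcat_km", "ref_kcat_km",
           "ratio", "excess", "percent_change", "ratio_display",
           "excess_display", "percent_display", "measured") |>
    as_tibble()
}

#' Published comparison claims for the BT4131 panel
#'
#' The ten fold/percent-change comparisons reported in the published
#' characterization of the BT4131 variants. Fold-increase claims use either
#' the excess convention (`ratio - 1`; e.g. M1's "1.4-fold increase" on
#' GlcNAc6P) or the plain ratio (M4's "9.5-fold increase"); percent claims
#' are printed to 1 decimal except M4's Glc6P decrease, printed as an
#' integer. Each claim row pins its own convention and printed precision.
#'
#' @return A tibble with columns `variant`, `substrate`, `reference`,
#'   `convention` (`"ratio"`, `"excess"` or `"percent"`), `digits`
#'   (printed decimals), `reported` (the printed number, signed as a
#'   change for percents).
#' @export
reported_preference_claims <- function() {
  tibble::tribble(
    ~variant, ~substrate,  ~reference, ~convention, ~digits, ~reported,
    "M1",     "GlcNAc6P",  "WT",       "excess",    1L,       1.4,
    "M1",     "Glc6P",     "WT",       "percent",   1L,     -63.5,
    "M1",     "Fru6P",     "WT",       "percent",   1L,     -73.1,
    "M2",     "GlcNAc6P",  "WT",       "excess",    1L,       4.1,
    "M2",     "Glc6P",     "M1",       "excess",    1L,       3.1,
    "M2",     "Glc6P",     "WT",       "percent",   1L,      49.7,
    "M3",     "GlcNAc6P",  "WT",       "excess",    1L,       4.6,
    "M3",     "Glc6P",     "WT",       "percent",   1L,     -60.6,
    "M4",     "GlcNAc6P",  "WT",       "ratio",     1L,       9.5,
    "M4",     "Glc6P",     "WT",       "percent",   0L,     -59
  )
}

#' Check a panel against the published comparison claims
#'
#' Recomputes each claim in [reported_preference_claims()] from the panel with
#' the claim's own convention, rounds to the printed precision (round half
#' up) and compares with the printed number. With the packaged
#' [bt4131_panel()] all ten claims agree.
#'
#' @param panel A `kinetic_panel`; defaults to the packaged BT4131 panel.
#' @param claims A claims table in the format of
#'   [reported_preference_claims()].
#' @return A tibble of claims with `computed` (raw), `displayed` (rounded to
#'   printed precision) and `pass` columns.
#' @examples
#' all(check_reported_changes()$pass)
#' @export
check_reported_changes <- function(panel = bt4131_panel(),
                                   claims = reported_preference_claims()) {
  panel <- if (inherits(panel, "kinetic_panel")) panel else kinetic_panel(panel)
  lookup <- function(variant, substrate) {
    hit <- panel[panel$variant == variant & panel$substrate == substrate, ]
    if (nrow(hit) != 1 || !hit$measured) {
      abort(sprintf("panel has no measured entry for (%s, %s).",
                    variant, substrate), class = "phosflux_data_error")
    }
    hit$kcat_km
  }
  claims |>
    mutate(
      computed = purrr::pmap_dbl(
        list(.data$variant, .data$substrate, .data$reference,
             .data$convention),
        function(variant, substrate, reference, convention) {
          fc <- fold_change(lookup(variant, substrate),
                            lookup(reference, substrate))
          switch(convention,
                 ratio = fc$ratio,
                 excess = fc$excess,
                 percent = fc$percent_change,
                 abort(sprintf("unknown convention '%s'.", convention),
                       class = "phosflux_config_error"))
        }),
      displayed = round_half_up(.data$computed, .data$digits),
      pass = .data$displayed == .data$reported
    )
}
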