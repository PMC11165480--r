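#' Read / write tidy velocity CSVs
#'
#' The velocity dialect carries columns
#' `variant,substrate,substrate_conc_mM,velocity,replicate`. Values are
#' written at full double precision, so a write/read round trip is lossless
#' well beyond 12 significant digits.
#'
#' @param path File path.
#' @return `read_velocity_csv()` returns a validated tibble.
#' @export
read_velocity_csv <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      variant = readr::col_character(),
      substrate = readr::col_character(),
      substrate_conc_mM = readr::col_double(),
      velocity = readr::col_double(),
      replicate = readr::col_integer()
    ))
  probs <- readr::problems(data)
  if (nrow(probs)) {
    abort(sprintf("malformed velocity CSV: %s (row %d, column %s).",
                  probs$expected[1], probs$row[1], probs$col[1]),
          class = "phosflux_data_error")
  }
  require_columns(data, c("variant", "substrate", "substrate_conc_mM",
                          "velocity", "replicate"), "velocity CSV")
  if (nrow(data) == 0) {
    abort("velocity CSV contains no observations.",
          class = "phosflux_data_error")
  }
  data
}

#' @param data A tidy velocity table.
#' @rdname read_velocity_csv
#' @export
write_velocity_csv <- function(data, path) {
  require_columns(data, c("variant", "substrate", "substrate_conc_mM",
                          "velocity", "replicate"), "velocity data")
  readr::write_csv(data, path)
  invisible(path)
}

#' Write ensemble outputs to a directory
#'
#' Writes `summary.csv` (the per-draw, per-variant summaries),
#' `comparison.csv` (the paired variant comparison) and `provenance.json`
#' (sampling spec, variants, mode flags, seed and package version) so a run
#' is reconstructible from its outputs alone. The two CSVs are byte-stable
#' under a fixed seed.
#'
#' @param ensemble A `pathway_ensemble`.
#' @param dir Output directory (created if missing).
#' @param reference Reference variant for the comparison table.
#' @return Invisibly, the directory path.
#' @export
write_ensemble <- function(ensemble, dir, reference = "WT") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(ensemble$summaries, file.path(dir, "summary.csv"))
  readr::write_csv(compare_variants(ensemble, reference),
                   file.path(dir, "comparison.csv"))
  prov <- list(
    sampling = unclass(ensemble$spec),
    variants = ensemble$variants,
    horizon = ensemble$horizon,
    modes = list(v10_substrate = ensemble$v10_substrate,
                 basal_mult = ensemble$basal_mult),
    package_version = as.character(utils::packageVersion("phosflux"))
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

config_allowed <- list(
  top = c("sampling", "variants", "ratio_table", "horizon", "initial_state",
          "modes"),
  sampling = c("n_draws", "seed", "km_nonphos_range", "km_wt_glc6p_range",
               "vmax_nonphos_range", "vmax_glc6p_wt", "v1max",
               "hill_n_range", "ka_range", "ki_range", "shared_hill"),
  modes = c("v10_substrate", "basal_mult", "impute")
)

#' Read and validate an ensemble configuration document
#'
#' A JSON document with blocks `sampling` (any [sampling_spec()] argument),
#' `variants`, `ratio_table` (a CSV path in the panel dialect, or inline
#' rows with `variant,substrate,vmax_ratio,km_ratio`), `horizon`,
#' `initial_state` (eight values) and `modes` (`v10_substrate`,
#' `basal_mult`, `impute`). Unknown keys are rejected by name.
#'
#' @param path Path to the JSON document.
#' @return A validated config list consumable by [run_ensemble_config()].
#' @export
read_ensemble_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys <- function(obj, allowed, where) {
    unknown <- setdiff(names(obj), allowed)
    if (length(unknown)) {
      abort(sprintf("unknown key '%s' in %s.", unknown[1], where),
            class = "phosflux_config_error")
    }
  }
  check_keys(cfg, config_allowed$top, "config")
  if (!is.null(cfg$sampling)) {
    check_keys(cfg$sampling, config_allowed$sampling, "config$sampling")
  }
  if (!is.null(cfg$modes)) {
    check_keys(cfg$modes, config_allowed$modes, "config$modes")
  }
  if (!is.null(cfg$initial_state) && length(cfg$initial_state) != 8) {
    abort("`initial_state` must have 8 components.",
          class = "phosflux_config_error")
  }
  cfg
}

#' Run an ensemble from a configuration document
#'
#' @param config A config list from [read_ensemble_config()].
#' @param out Optional output directory passed to [write_ensemble()].
#' @return The `pathway_ensemble`.
#' @export
run_ensemble_config <- function(config, out = NULL) {
  spec <- do.call(sampling_spec, as.list(config$sampling))
  ratios <- if (is.null(config$ratio_table)) {
    default_ratio_table(
      impute = unlist(config$modes$impute) %||% NULL)
  } else if (is.character(config$ratio_table)) {
    default_ratio_table(read_panel_csv(config$ratio_table),
                        impute = unlist(config$modes$impute) %||% NULL)
  } else {
    as_tibble(config$ratio_table) |>
      mutate(provenance = "supplied")
  }
  ens <- run_ensemble(
    spec,
    variants = config$variants %||% c("WT", "M1", "M2", "M3"),
    ratios = ratios,
    horizon = config$horizon %||% 200,
    initial = config$initial_state %||% rep(0, 8),
    v10_substrate = config$modes$v10_substrate %||% "x4",
    basal_mult = config$modes$basal_mult %||% 1
  )
  if (!is.null(out)) write_ensemble(ens, out)
  ens
}
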