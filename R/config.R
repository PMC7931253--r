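#' Pipeline configuration
#'
#' Aggregates every tunable constant of the pipeline: Atwater factors, the
#' daily reference, exchange quanta, Wheeler band cut points, reporting
#' modes and audit tolerances. Defaults reproduce the packaged reference
#' tables.
#'
#' @param atwater [atwater_factors()].
#' @param reference [daily_reference()].
#' @param quanta [exchange_quantum()].
#' @param bands [wheeler_bands()].
#' @param dv_rounding `"truncate"` or `"half_up"` for %DV reporting.
#' @param closure_tol,energy_tol audit tolerances in g / kcal.
#' @param seed integer seed for `simulate`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(atwater = atwater_factors(),
                            reference = daily_reference(),
                            quanta = exchange_quantum(),
                            bands = wheeler_bands(),
                            dv_rounding = c("truncate", "half_up"),
                            closure_tol = 0.2, energy_tol = 1.5,
                            seed = 1L) {
  dv_rounding <- match.arg(dv_rounding)
  if (closure_tol <= 0 || energy_tol <= 0) {
    abort_foodexch("invalid_component", "tolerances must be > 0")
  }
  structure(list(atwater = atwater, reference = reference, quanta = quanta,
                 bands = bands, dv_rounding = dv_rounding,
                 closure_tol = closure_tol, energy_tol = energy_tol,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write pipeline configuration as YAML
#'
#' The YAML round-trips: `read_config(write_config(cfg, path))` equals
#' `cfg`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(
    atwater = unclass(config$atwater),
    reference = unclass(config$reference),
    quanta = unclass(config$quanta),
    bands = lapply(unclass(config$bands), function(b)
      list(cuts = b$cuts, servings = b$servings)),
    dv_rounding = config$dv_rounding,
    closure_tol = config$closure_tol,
    energy_tol = config$energy_tol,
    seed = config$seed)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort_foodexch("schema_error", sprintf("config file not found: %s", path))
  }
  y <- yaml::read_yaml(path)
  pipeline_config(
    atwater = do.call(atwater_factors, stats::setNames(
      y$atwater, c("cho_kcal_per_g", "protein_kcal_per_g", "fat_kcal_per_g"))),
    reference = do.call(daily_reference, y$reference[c("cho_g", "protein_g",
                                                       "fat_g", "energy_kcal")]),
    quanta = do.call(exchange_quantum, stats::setNames(
      y$quanta, c("cho_g", "protein_g", "fat_g"))),
    bands = wheeler_bands(
      cho_cuts = y$bands$cho$cuts, cho_servings = y$bands$cho$servings,
      protein_cuts = y$bands$protein$cuts,
      protein_servings = y$bands$protein$servings,
      fat_cuts = y$bands$fat$cuts, fat_servings = y$bands$fat$servings),
    dv_rounding = y$dv_rounding,
    closure_tol = y$closure_tol, energy_tol = y$energy_tol,
    seed = y$seed)
}
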