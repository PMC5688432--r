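# Run-configuration reading and validation. A run configuration is a YAML
# file naming a bundled preset (or giving inline inputs on the percent
# scale, same keys as the preset files), optional outcome-parameter
# overrides, one or more scenario definitions, and output options. All
# percent-scale values are converted to proportions here, at the boundary.

config_allowed_top <- c("preset", "inputs", "parameters", "scenarios",
                        "output")
config_allowed_params <- c("mu", "sigma", "rho", "alpha")
config_allowed_scenario <- c("name", "years", "cpr", "proportion_married",
                             "ppi_months", "pct_childless_45_49",
                             "unmet_need", "effectiveness", "sigma", "women")
# Trajectory values for these scenario fields are written on the percent
# scale in config files.
config_pct_fields <- c("cpr", "proportion_married", "unmet_need",
                       "effectiveness")

#' Read and validate a run configuration
#'
#' Parses a YAML run configuration, validates every field against the
#' model's domain constraints (reporting the offending key and allowed
#' range), converts percent-scale values to proportions, and assembles the
#' preset, outcome parameters and scenario objects needed for a projection.
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `"fp_run_config"` with elements `preset`
#'   (an `fp_preset`), `params` (outcome parameters after overrides),
#'   `scenarios` (named list of [scenario()] objects), `rounding` (report
#'   granularity, `NULL` for none), and `raw` (the parsed file).
#' @examples
#' cfg <- read_config(system.file("extdata", "configs", "mali.yaml",
#'                                package = "famplanr"))
#' names(cfg$scenarios)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    fp_abort_config(sprintf("Configuration file not found: '%s'.", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      fp_abort_config(sprintf("Cannot parse '%s' as YAML: %s", path,
                              conditionMessage(e)))
    }
  )
  if (!is.list(raw)) {
    fp_abort_config("Configuration must be a YAML mapping.")
  }
  unknown <- setdiff(names(raw), config_allowed_top)
  if (length(unknown) > 0) {
    fp_abort_config(sprintf(
      "Unknown configuration key(s): %s. Allowed keys: %s.",
      paste(unknown, collapse = ", "),
      paste(config_allowed_top, collapse = ", ")
    ))
  }

  # Preset, possibly with inline overrides.
  if (!is.null(raw$preset)) {
    preset <- load_preset(raw$preset)
    if (!is.null(raw$inputs)) {
      merged <- utils::modifyList(preset$raw, raw$inputs)
      preset <- preset_from_raw(merged)
    }
  } else if (!is.null(raw$inputs)) {
    preset <- preset_from_raw(raw$inputs)
  } else {
    fp_abort_config("Configuration needs a `preset` name or an `inputs` block.")
  }

  # Outcome-parameter overrides.
  p <- raw$parameters %||% list()
  unknown <- setdiff(names(p), config_allowed_params)
  if (length(unknown) > 0) {
    fp_abort_config(sprintf(
      "Unknown parameter key(s): %s. Allowed: %s.",
      paste(unknown, collapse = ", "),
      paste(config_allowed_params, collapse = ", ")
    ))
  }
  params <- outcome_parameters(
    mu = p$mu %||% preset$params$mu,
    sigma = p$sigma %||% preset$params$sigma,
    rho = p$rho %||% preset$params$rho,
    alpha = p$alpha %||% preset$params$alpha
  )
  preset$params <- params

  scenarios <- purrr::map(raw$scenarios %||% list(), parse_scenario)
  names(scenarios) <- purrr::map_chr(scenarios, "name")

  rounding <- raw$output$rounding
  if (!is.null(rounding)) check_range(rounding, "output$rounding", lower = 1)

  structure(
    list(preset = preset, params = params, scenarios = scenarios,
         rounding = rounding, raw = raw),
    class = "fp_run_config"
  )
}

parse_scenario <- function(s) {
  unknown <- setdiff(names(s), config_allowed_scenario)
  if (length(unknown) > 0) {
    fp_abort_config(sprintf(
      "Unknown scenario key(s): %s. Allowed: %s.",
      paste(unknown, collapse = ", "),
      paste(config_allowed_scenario, collapse = ", ")
    ))
  }
  if (is.null(s$name) || is.null(s$years)) {
    fp_abort_config("Every scenario needs `name` and `years` (start, end).")
  }
  if (is.null(s$years$start) || is.null(s$years$end)) {
    fp_abort_config(sprintf(
      "Scenario '%s': `years` must give `start` and `end`.", s$name
    ))
  }
  args <- list(name = s$name, years = c(s$years$start, s$years$end))
  for (field in setdiff(config_allowed_scenario, c("name", "years"))) {
    if (!is.null(s[[field]])) {
      args[[field]] <- parse_trajectory(s[[field]], field, s$name)
    }
  }
  do.call(scenario, args)
}

parse_trajectory <- function(tr, field, scenario_name) {
  pct <- field %in% config_pct_fields
  scale <- function(x) if (pct) x / 100 else x
  if (!is.list(tr) || is.null(tr$type)) {
    fp_abort_config(sprintf(
      "Scenario '%s', field '%s': trajectory needs a `type` (constant, ramp, series).",
      scenario_name, field
    ))
  }
  switch(
    tr$type,
    constant = traj_constant(if (is.null(tr$value)) NULL else scale(tr$value)),
    ramp = traj_ramp(
      points_per_year = tr$points_per_year %||%
        fp_abort_config(sprintf(
          "Scenario '%s', field '%s': ramp needs `points_per_year`.",
          scenario_name, field
        )),
      start = if (is.null(tr$start)) NULL else scale(tr$start),
      cap = scale(tr$cap %||% if (pct) 85 else Inf)
    ),
    series = traj_series(unlist(tr$years), scale(unlist(tr$values))),
    fp_abort_config(sprintf(
      "Scenario '%s', field '%s': unknown trajectory type '%s'.",
      scenario_name, field, tr$type
    ))
  )
}

#' Write a run configuration back to YAML
#'
#' Writes the raw (percent-scale) representation, so that
#' `read_config(write_config(cfg, path))` reproduces the configuration
#' exactly.
#'
#' @param config An `fp_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fp_run_config"))
  yaml::write_yaml(config$raw, path, precision = 15)
  invisible(path)
}
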