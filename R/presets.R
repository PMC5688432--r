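#' Load a bundled country preset
#'
#' Presets bundle the key reproductive indicators for four illustrative
#' countries spanning the family-planning spectrum — Mali (low use, high
#' fertility), Kenya (moderate use, medium fertility), Indonesia (high use,
#' low fertility), and Ukraine (very low fertility driven by traditional
#' methods and abortion) — together with published reference outputs used by
#' the test-suite. Percent-scale values are stored as published and converted
#' to proportions on load. The all-method contraceptive prevalence is the sum
#' of modern and traditional prevalence, with traditional methods carrying
#' their standard 78% failure rate in the average-effectiveness table;
#' the preset's published average effectiveness overrides a mix-derived
#' value.
#'
#' The women-of-reproductive-age scaffold is synthetic: it is back-solved so
#' that [births_from_tfr()] reproduces the published birth count at baseline
#' (`W = B * 35 / TFR`).
#'
#' @param name Preset name (case-insensitive): `"Mali"`, `"Kenya"`,
#'   `"Indonesia"`, or `"Ukraine"`; or pass `path` instead.
#' @param path Path to a preset YAML file; overrides `name`.
#' @return A list of class `"fp_preset"` with elements
#'   `name`, `baseline_year`, `observed_tfr`, `inputs` (a
#'   [proximate_inputs()] tibble on the proportion scale), `params`
#'   ([outcome_parameters()] with the country stillbirth rate), `population`
#'   (women of reproductive age, married women, contraceptive users, women
#'   with unmet need), `unmet_need`, `abortions_per_1000_women`, `scenario`
#'   (published scale-up start and slope), `reference` (published outputs),
#'   and `raw` (the parsed file, percent scale).
#' @examples
#' mali <- load_preset("Mali")
#' mali$inputs
#' @export
load_preset <- function(name = NULL, path = NULL) {
  if (is.null(path)) {
    if (is.null(name)) {
      fp_abort_input("Supply a preset `name` or a `path`.")
    }
    available <- preset_names()
    idx <- match(tolower(name), tolower(available))
    if (is.na(idx)) {
      fp_abort_lookup(sprintf(
        "Unknown preset '%s'. Available presets: %s.",
        name, paste(available, collapse = ", ")
      ))
    }
    path <- system.file("extdata", "presets",
                        paste0(tolower(available[idx]), ".yaml"),
                        package = "famplanr")
  }
  if (!file.exists(path)) {
    fp_abort_config(sprintf("Preset file not found: '%s'.", path))
  }
  raw <- yaml::read_yaml(path)
  preset_from_raw(raw)
}

preset_names <- function() {
  files <- list.files(
    system.file("extdata", "presets", package = "famplanr"),
    pattern = "\\.yaml$"
  )
  vapply(files, function(f) {
    nm <- sub("\\.yaml$", "", f)
    paste0(toupper(substring(nm, 1, 1)), substring(nm, 2))
  }, character(1), USE.NAMES = FALSE)
}

preset_required_keys <- c(
  "name", "baseline_year", "total_fertility_rate", "modern_cpr_pct",
  "traditional_cpr_pct", "unmet_need_pct", "proportion_married_pct",
  "ppi_months", "pct_childless_45_49", "abortions_per_1000_women",
  "stillbirth_rate_per_1000", "effectiveness_pct"
)

# Build the validated, proportion-scale preset object from a parsed file.
preset_from_raw <- function(raw) {
  missing <- setdiff(preset_required_keys, names(raw))
  if (length(missing) > 0) {
    fp_abort_config(sprintf(
      "Preset is missing required key(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  tfr <- check_range(raw$total_fertility_rate, "total_fertility_rate",
                     lower = 0, open_lower = TRUE)
  cpr <- (raw$modern_cpr_pct + raw$traditional_cpr_pct) / 100
  unmet <- check_range(raw$unmet_need_pct, "unmet_need_pct", 0, 100) / 100
  pm <- check_range(raw$proportion_married_pct, "proportion_married_pct",
                    0, 100) / 100
  eff <- check_range(raw$effectiveness_pct, "effectiveness_pct", 0, 100) / 100
  tar <- tar_from_abortion_rate(raw$abortions_per_1000_women)

  inputs <- proximate_inputs(
    proportion_married = pm,
    ppi_months = raw$ppi_months,
    pct_childless_45_49 = raw$pct_childless_45_49,
    cpr = cpr,
    effectiveness = eff,
    tar = tar,
    tfr_for_ca = tfr
  )

  ref <- if (is.null(raw$reference_outputs)) NULL else
    as_tibble(raw$reference_outputs)
  # Synthetic scaffold: women of reproductive age back-solved from published
  # births so the crude conversion is exact at baseline; an explicit
  # women_reproductive_age key takes precedence.
  women <- raw$women_reproductive_age %||% (ref$births * 35 / tfr)
  if (is.null(women)) {
    fp_abort_config(
      "Preset needs either `women_reproductive_age` or `reference_outputs$births`."
    )
  }
  married <- pm * women
  population <- list(
    women_reproductive_age = women,
    women_married = married,
    contraceptive_users = cpr * married,
    unmet_need_women = unmet * married
  )

  params <- outcome_parameters(
    sigma = raw$stillbirth_rate_per_1000,
    alpha = 0 # calibrated later from the observed abortion rate
  )

  scenario <- list(
    start_cpr = (raw$scenario_start_cpr_pct %||% (cpr * 100)) / 100,
    ramp_points_per_year = raw$scenario_ramp_points_per_year %||% 1
  )

  structure(
    list(
      name = raw$name,
      baseline_year = raw$baseline_year,
      observed_tfr = tfr,
      inputs = inputs,
      params = params,
      population = population,
      unmet_need = unmet,
      abortions_per_1000_women = raw$abortions_per_1000_women,
      scenario = scenario,
      reference = ref,
      raw = raw
    ),
    class = "fp_preset"
  )
}

#' @export
print.fp_preset <- function(x, ...) {
  cat(sprintf("<fp_preset: %s, baseline %s>\n", x$name, x$baseline_year))
  cat(sprintf("  TFR %.2f | CPR %.0f%% | effectiveness %.0f%% | unmet need %.0f%%\n",
              x$observed_tfr, 100 * x$inputs$cpr,
              100 * x$inputs$effectiveness, 100 * x$unmet_need))
  cat(sprintf("  women 15-49 (synthetic scaffold): %s\n",
              format(round(x$population$women_reproductive_age), big.mark = ",")))
  invisible(x)
}

#' Write a preset back to YAML
#'
#' Writes the percent-scale representation (`$raw`) so a written preset
#' re-reads bit-identically through [load_preset()].
#'
#' @param preset An `fp_preset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preset <- function(preset, path) {
  stopifnot(inherits(preset, "fp_preset"))
  yaml::write_yaml(preset$raw, path, precision = 15)
  invisible(path)
}

#' Default parameter ranges for synthetic populations
#'
#' Ranges span the variety of the bundled presets: from high-fertility,
#' low-use settings to low-fertility, high-use ones. The contraception-index
#' domain constraint `1.08 * cpr * e < 1` holds across the whole box
#' (1.08 * 0.8 * 0.99 = 0.856), so every draw is feasible.
#'
#' @return A named list of `c(min, max)` ranges.
#' @export
synth_ranges <- function() {
  list(
    total_fertility_rate = c(1.2, 7),
    proportion_married = c(0.4, 0.95),
    ppi_months = c(1.5, 18),
    pct_childless_45_49 = c(0.5, 6),
    cpr = c(0.02, 0.8),
    effectiveness = c(0.85, 0.99),
    abortions_per_1000_women = c(0, 60),
    unmet_need = c(0.03, 0.3),
    women_reproductive_age = c(1e6, 5e7),
    stillbirth_rate_per_1000 = c(5, 45)
  )
}

#' Generate a synthetic population preset
#'
#' Draws one population uniformly from the given parameter ranges,
#' deterministically for a given seed. Useful for property-style testing:
#' every generated preset satisfies the type invariants of the model
#' (proportions in range, `1.08 * CPR * e < 1`, non-negative counts).
#'
#' @param seed Integer seed; the same seed always yields the same preset.
#' @param ranges Named list of `c(min, max)` ranges, as [synth_ranges()].
#'   Pin a parameter by giving a zero-width range.
#' @return An `fp_preset` (with synthetic reference outputs computed from
#'   the model itself).
#' @examples
#' synth_population(1)
#' @export
synth_population <- function(seed, ranges = synth_ranges()) {
  defaults <- synth_ranges()
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown) > 0) {
    fp_abort_input(sprintf(
      "Unknown range name(s): %s.", paste(unknown, collapse = ", ")
    ))
  }
  ranges <- utils::modifyList(defaults, ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2 || anyNA(r) || r[1] > r[2]) {
      fp_abort_input(sprintf("Range `%s` must be c(min, max) with min <= max.", nm))
    }
  }
  if (1.08 * ranges$cpr[2] * ranges$effectiveness[2] >= 1) {
    fp_abort_input(
      "Infeasible ranges: 1.08 * max(cpr) * max(effectiveness) must stay below 1."
    )
  }
  draw <- withr::with_seed(seed, {
    lapply(ranges, function(r) stats::runif(1, r[1], r[2]))
  })

  tfr <- draw$total_fertility_rate
  women <- draw$women_reproductive_age
  births <- births_from_tfr(tfr, women)
  raw <- list(
    name = sprintf("Synthetic-%d", as.integer(seed)),
    baseline_year = 2015,
    total_fertility_rate = tfr,
    modern_cpr_pct = draw$cpr * 100,
    traditional_cpr_pct = 0,
    unmet_need_pct = draw$unmet_need * 100,
    proportion_married_pct = draw$proportion_married * 100,
    ppi_months = draw$ppi_months,
    pct_childless_45_49 = draw$pct_childless_45_49,
    abortions_per_1000_women = draw$abortions_per_1000_women,
    stillbirth_rate_per_1000 = draw$stillbirth_rate_per_1000,
    effectiveness_pct = draw$effectiveness * 100,
    scenario_start_cpr_pct = draw$cpr * 100,
    scenario_ramp_points_per_year = 1,
    reference_outputs = list(births = births)
  )
  preset <- preset_from_raw(raw)
  # Synthetic reference outcomes come from the model itself so the preset is
  # internally consistent (abortions <= unintended by construction).
  u <- unintended_pregnancies(
    preset$population$contraceptive_users, draw$effectiveness,
    preset$population$unmet_need_women, rho = preset$params$rho
  )
  alpha <- withr::with_seed(seed + 1L, stats::runif(1, 0, 1))
  a <- abortions_from_unintended(u$total, alpha)
  s <- stillbirths_from_births(births, preset$params$sigma)
  m <- miscarriages_from_outcomes(births, a, s, preset$params$mu)
  out <- assemble_outcomes(births, a, m, s, u$from_failure, u$from_unmet_need)
  preset$reference <- dplyr::rename(
    out[, c("pregnancies", "unintended_total", "births", "miscarriages",
            "stillbirths", "abortions")],
    unintended_pregnancies = "unintended_total"
  )
  preset$raw$reference_outputs <- as.list(preset$reference)
  preset
}
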