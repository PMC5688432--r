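#' Input trajectories for scenario projection
#'
#' A trajectory describes how one model input evolves over the projection
#' years:
#'
#' * `traj_constant()` holds the input at a fixed value (the baseline value
#'   when `value` is `NULL`).
#' * `traj_ramp()` increases the input linearly by `points_per_year`
#'   percentage points per year from `start` (baseline when `NULL`), capped
#'   at `cap` to keep the contraception index positive and reflect
#'   saturation of demand.
#' * `traj_series()` passes through explicit `(year, value)` anchor points,
#'   linearly interpolated between anchors and held flat outside them.
#'
#' Slopes and caps for prevalence-type inputs are expressed in percentage
#' points per year on the percent scale, matching how survey trends are
#' reported; values themselves are proportions.
#'
#' @param value Constant value (proportion scale), or `NULL` for baseline.
#' @param points_per_year Ramp slope in percentage points per year.
#' @param start Ramp starting value as a proportion; `NULL` for baseline.
#' @param cap Maximum value the ramp may reach (default 0.85).
#' @param years,values Anchor years and values for an explicit series.
#' @return A trajectory object of class `"fp_trajectory"`.
#' @examples
#' traj_ramp(points_per_year = 2, start = 0.10)
#' traj_series(years = c(2015, 2020, 2025), values = c(0.10, 0.18, 0.22))
#' @name trajectories
NULL

#' @rdname trajectories
#' @export
traj_constant <- function(value = NULL) {
  if (!is.null(value)) check_numeric(value, "value")
  structure(list(type = "constant", value = value), class = "fp_trajectory")
}

#' @rdname trajectories
#' @export
traj_ramp <- function(points_per_year, start = NULL, cap = 0.85) {
  check_numeric(points_per_year, "points_per_year")
  if (!is.null(start)) check_numeric(start, "start")
  check_numeric(cap, "cap")
  structure(list(type = "ramp", points_per_year = points_per_year,
                 start = start, cap = cap),
            class = "fp_trajectory")
}

#' @rdname trajectories
#' @export
traj_series <- function(years, values) {
  check_numeric(years, "years")
  check_numeric(values, "values")
  if (length(years) != length(values) || length(years) < 1) {
    fp_abort_input("`years` and `values` must be equal-length and non-empty.")
  }
  if (is.unsorted(years, strictly = TRUE)) {
    fp_abort_input("`years` must be strictly increasing.")
  }
  structure(list(type = "series", years = years, values = values),
            class = "fp_trajectory")
}

# Evaluate a trajectory over the projection years given its baseline value.
eval_trajectory <- function(traj, years, baseline) {
  stopifnot(inherits(traj, "fp_trajectory"))
  switch(
    traj$type,
    constant = rep(traj$value %||% baseline, length(years)),
    ramp = {
      start <- traj$start %||% baseline
      # percent-scale arithmetic so integer-point ramps land on exact values
      pmin((start * 100 + (years - years[1]) * traj$points_per_year) / 100,
           traj$cap)
    },
    series = stats::approx(traj$years, traj$values, xout = years,
                           rule = 2)$y
  )
}

#' Define a projection scenario
#'
#' A scenario names an inclusive year range and a trajectory for each input
#' that may change over time. Inputs without an explicit trajectory stay at
#' their baseline value, with one exception: when contraceptive prevalence
#' changes and no unmet-need trajectory is given, each additional user is
#' drawn from the unmet-need pool,
#' `unmet(t) = max(0, unmet(t0) - (cpr(t) - cpr(t0)))`. Because typical
#' method failure (1 - e, around 5%) is far below the pregnancy rate of
#' women with unmet need (31%), contraceptive scale-up then reduces
#' unintended pregnancies and abortions, as observed in practice. Hold unmet
#' need fixed explicitly with `unmet_need = traj_constant()` to disable the
#' coupling.
#'
#' @param name Scenario label.
#' @param years Projection years: an inclusive integer range (`c(start,
#'   end)` or a full sequence).
#' @param cpr,proportion_married,ppi_months,pct_childless_45_49,effectiveness,sigma,women
#'   Trajectories ([traj_constant()], [traj_ramp()], [traj_series()]) for
#'   contraceptive prevalence, proportion married, postpartum
#'   insusceptibility, percent childless at 45--49, average effectiveness,
#'   the stillbirth rate, and women of reproductive age.
#' @param unmet_need Trajectory for unmet need, or `NULL` (default) for the
#'   CPR-coupled behaviour described above.
#' @return A list of class `"fp_scenario"`.
#' @examples
#' scenario("scale-up", years = c(2015, 2025),
#'          cpr = traj_ramp(points_per_year = 2, start = 0.10))
#' @export
scenario <- function(name, years,
                     cpr = traj_constant(),
                     proportion_married = traj_constant(),
                     ppi_months = traj_constant(),
                     pct_childless_45_49 = traj_constant(),
                     unmet_need = NULL,
                     effectiveness = traj_constant(),
                     sigma = traj_constant(),
                     women = traj_constant()) {
  check_numeric(years, "years")
  if (length(years) < 2 || any(years != floor(years))) {
    fp_abort_input("`years` must give an inclusive integer range.")
  }
  years <- seq(min(years), max(years))
  trajs <- list(cpr = cpr, proportion_married = proportion_married,
                ppi_months = ppi_months,
                pct_childless_45_49 = pct_childless_45_49,
                effectiveness = effectiveness, sigma = sigma, women = women)
  for (nm in names(trajs)) {
    if (!inherits(trajs[[nm]], "fp_trajectory")) {
      fp_abort_input(sprintf("`%s` must be a trajectory object.", nm))
    }
  }
  if (!is.null(unmet_need) && !inherits(unmet_need, "fp_trajectory")) {
    fp_abort_input("`unmet_need` must be a trajectory object or NULL.")
  }
  structure(c(list(name = name, years = years, unmet_need = unmet_need),
              trajs),
            class = "fp_scenario")
}

#' Calibrate a baseline for projection
#'
#' Fixes the two constants of a projection from one complete baseline year:
#' total fecundity `TF` (via [calibrate_total_fecundity()], resolving the
#' abortion-index circularity with the observed TFR as a fixed point) and
#' the abortion proportion `alpha` (via [calibrate_alpha()]).
#'
#' `alpha` is calibrated from, in order of preference: the explicit
#' `observed_abortions`/`observed_unintended` arguments; the preset's
#' published abortion and unintended-pregnancy counts; or the preset's
#' abortion rate per 1000 women converted to a count with the population
#' scaffold, paired with the model-computed unintended pregnancies.
#'
#' @param preset An [load_preset()] / [synth_population()] object.
#' @param observed_abortions Optional observed induced-abortion count.
#' @param observed_unintended Optional observed unintended-pregnancy count.
#' @return A list of class `"fp_calibration"`: the baseline inputs, `tf`,
#'   `alpha`, `effectiveness`, outcome `params` (with `alpha` filled in),
#'   population scaffold, and baseline year. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @examples
#' cal <- calibrate_baseline(load_preset("Mali"))
#' glance(cal)
#' @export
calibrate_baseline <- function(preset, observed_abortions = NULL,
                               observed_unintended = NULL) {
  stopifnot(inherits(preset, "fp_preset"))
  inputs <- preset$inputs
  tf <- calibrate_total_fecundity(inputs, preset$observed_tfr)

  pop <- preset$population
  u_model <- unintended_pregnancies(
    pop$contraceptive_users, inputs$effectiveness,
    pop$unmet_need_women, rho = preset$params$rho
  )
  ref <- preset$reference
  a_obs <- observed_abortions %||% ref$abortions %||%
    (preset$abortions_per_1000_women / 1000 * pop$women_reproductive_age)
  u_obs <- observed_unintended %||% ref$unintended_pregnancies %||%
    u_model$total
  alpha <- calibrate_alpha(a_obs, u_obs)

  params <- preset$params
  params$alpha <- alpha

  structure(
    list(
      preset_name = preset$name,
      baseline_year = preset$baseline_year,
      observed_tfr = preset$observed_tfr,
      inputs = inputs,
      tf = tf,
      alpha = alpha,
      effectiveness = inputs$effectiveness,
      params = params,
      population = pop,
      unmet_need = preset$unmet_need
    ),
    class = "fp_calibration"
  )
}

#' @export
print.fp_calibration <- function(x, ...) {
  cat(sprintf("<fp_calibration: %s, baseline %s>\n", x$preset_name,
              x$baseline_year))
  cat(sprintf("  TF = %.3f births/woman | alpha = %.3f | e = %.3f\n",
              x$tf, x$alpha, x$effectiveness))
  invisible(x)
}

#' Project fertility and pregnancy outcomes over a scenario
#'
#' Steps the model through each scenario year: inputs are updated along
#' their trajectories; the five indices are computed, the abortion index
#' using the previous year's TFR and prevalence (at the first year, the
#' calibrated baseline values); the TFR is recomposed with the constant
#' calibrated total fecundity; and the pregnancy-outcome accounting is
#' evaluated with the constant calibrated abortion proportion. The model is
#' fully deterministic.
#'
#' @param calibration An [calibrate_baseline()] object.
#' @param scn An [scenario()] object.
#' @return A tibble of class `"fp_projection"`, one row per year, with the
#'   evolving inputs, the five indices, `tfr`, and all outcome counts.
#'   Attributes `tf`, `alpha` and `scenario_name` record the calibration.
#' @examples
#' cal <- calibrate_baseline(load_preset("Mali"))
#' proj <- project(cal, scenario("constant", c(2015, 2025)))
#' proj[, c("year", "cpr", "tfr", "births", "abortions")]
#' @export
project <- function(calibration, scn) {
  stopifnot(inherits(calibration, "fp_calibration"),
            inherits(scn, "fp_scenario"))
  years <- scn$years
  n <- length(years)
  base <- calibration$inputs
  pop <- calibration$population

  cpr <- eval_trajectory(scn$cpr, years, base$cpr)
  pm <- eval_trajectory(scn$proportion_married, years, base$proportion_married)
  ppi <- eval_trajectory(scn$ppi_months, years, base$ppi_months)
  childless <- eval_trajectory(scn$pct_childless_45_49, years,
                               base$pct_childless_45_49)
  eff <- eval_trajectory(scn$effectiveness, years, base$effectiveness)
  sigma <- eval_trajectory(scn$sigma, years, calibration$params$sigma)
  women <- eval_trajectory(scn$women, years, pop$women_reproductive_age)
  unmet <- if (is.null(scn$unmet_need)) {
    pmax(0, calibration$unmet_need - (cpr - cpr[1]))
  } else {
    eval_trajectory(scn$unmet_need, years, calibration$unmet_need)
  }

  bad <- which(1.08 * cpr * eff >= 1)
  if (length(bad) > 0) {
    fp_abort_domain(sprintf(
      "Contraception index non-positive in year %d (cpr = %.3f, e = %.3f).",
      years[bad[1]], cpr[bad[1]], eff[bad[1]]
    ))
  }

  rows <- vector("list", n)
  tfr_prev <- calibration$observed_tfr
  cpr_prev <- base$cpr
  for (i in seq_len(n)) {
    inputs_i <- proximate_inputs(
      proportion_married = pm[i], ppi_months = ppi[i],
      pct_childless_45_49 = childless[i], cpr = cpr[i],
      effectiveness = eff[i], tar = base$tar,
      # lagged state drives the abortion index
      tfr_for_ca = tfr_prev
    )
    inputs_i$cpr_for_ca <- cpr_prev
    idx <- dplyr::mutate(
      compose_tfr(inputs_i, tf = calibration$tf),
      ca = index_abortion(.data$tfr_for_ca, .data$cpr_for_ca, .data$tar),
      tfr = .data$cm * .data$ci * .data$ca * .data$cs * .data$cc * .data$tf
    )

    married <- pm[i] * women[i]
    cu <- cpr[i] * married
    un <- unmet[i] * married
    params_i <- calibration$params
    params_i$sigma <- sigma[i]
    births <- births_from_tfr(idx$tfr, women[i])
    out <- pregnancy_outcomes(births, cu, un, eff[i], params_i)

    rows[[i]] <- dplyr::bind_cols(
      tibble(year = years[i], women_reproductive_age = women[i],
             unmet_need = unmet[i]),
      idx[, c("proportion_married", "ppi_months", "pct_childless_45_49",
              "cpr", "effectiveness", "tar",
              "cm", "ci", "ca", "cs", "cc", "tf", "tfr")],
      as_tibble(out)
    )
    tfr_prev <- idx$tfr
    cpr_prev <- cpr[i]
  }

  res <- dplyr::bind_rows(rows)
  attr(res, "tf") <- calibration$tf
  attr(res, "alpha") <- calibration$alpha
  attr(res, "scenario_name") <- scn$name
  attr(res, "preset_name") <- calibration$preset_name
  class(res) <- c("fp_projection", class(res))
  res
}

#' Compare two projection series
#'
#' Computes per-year and cumulative differences (scenario `b` minus
#' scenario `a`) in the outcome counts, e.g. an increasing-prevalence
#' scenario against a constant-prevalence counterfactual.
#'
#' @param a,b `fp_projection` tibbles over the same years.
#' @return A tibble of class `"fp_comparison"` with per-year differences
#'   (`d_*`) and running cumulative differences (`cum_d_*`) for births,
#'   abortions, miscarriages, stillbirths, pregnancies, and unintended
#'   pregnancies.
#' @examples
#' cal <- calibrate_baseline(load_preset("Mali"))
#' cst <- project(cal, scenario("constant", c(2015, 2025)))
#' up <- project(cal, scenario("scale-up", c(2015, 2025),
#'                             cpr = traj_ramp(2, start = 0.10)))
#' compare_scenarios(cst, up)
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "fp_projection"), inherits(b, "fp_projection"))
  if (!identical(a$year, b$year)) {
    fp_abort_input("Projections cover different year ranges; cannot compare.")
  }
  vars <- c("births", "abortions", "miscarriages", "stillbirths",
            "pregnancies", "unintended_total")
  diffs <- purrr::map(vars, ~ b[[.x]] - a[[.x]])
  names(diffs) <- paste0("d_", vars)
  cums <- purrr::map(diffs, cumsum)
  names(cums) <- paste0("cum_", names(diffs))
  res <- dplyr::bind_cols(tibble(year = a$year), as_tibble(diffs),
                          as_tibble(cums))
  attr(res, "scenario_a") <- attr(a, "scenario_name")
  attr(res, "scenario_b") <- attr(b, "scenario_name")
  class(res) <- c("fp_comparison", class(res))
  res
}
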