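#' Pregnancy-outcome model parameters
#'
#' Parameters of the pregnancy-outcome accounting extension:
#'
#' * `mu` — proportion of pregnancies ending in miscarriage (spontaneous
#'   loss before about 20 weeks). Default 0.13.
#' * `sigma` — stillbirths per 1000 live births (losses after about 20--28
#'   weeks). Default 19, the global average; country estimates vary widely.
#' * `rho` — annual pregnancy probability for a woman with unmet need for
#'   contraception. Default 0.31 (inter-quartile plausibility 0.23--0.38).
#' * `alpha` — proportion of unintended pregnancies terminated by induced
#'   abortion; usually calibrated from an observed abortion count via
#'   [calibrate_alpha()] and held constant over time.
#'
#' @param mu Miscarriage proportion in \[0, 1).
#' @param sigma Stillbirth rate per 1000 live births (>= 0).
#' @param rho Unmet-need pregnancy rate in \[0, 1\].
#' @param alpha Abortion proportion of unintended pregnancies in \[0, 1\].
#' @return A list of class `"fp_outcome_parameters"`.
#' @examples
#' outcome_parameters(sigma = 44)
#' @export
outcome_parameters <- function(mu = 0.13, sigma = 19, rho = 0.31, alpha = 0) {
  check_range(mu, "mu", 0, 1, open_upper = TRUE)
  check_nonnegative(sigma, "sigma")
  check_proportion(rho, "rho")
  check_proportion(alpha, "alpha")
  structure(list(mu = mu, sigma = sigma, rho = rho, alpha = alpha),
            class = "fp_outcome_parameters")
}

#' Crude live-birth count from a fertility rate
#'
#' Converts a total fertility rate into an annual number of live births as
#' `B = TFR * W / span`: each of the `W` women of reproductive age
#' contributes `TFR / span` births per year. This is a deliberately crude
#' stand-in for a full age-structured projection; callers with an externally
#' estimated birth count should supply it directly to downstream functions.
#'
#' @param tfr Total fertility rate (>= 0).
#' @param women_reproductive_age Number of women aged 15--49 (>= 0).
#' @param span_years Reproductive span in years (default 35).
#' @return Annual live births.
#' @examples
#' births_from_tfr(6.1, 4.2e6) # 732,000
#' @export
births_from_tfr <- function(tfr, women_reproductive_age, span_years = 35) {
  check_nonnegative(tfr, "tfr")
  check_nonnegative(women_reproductive_age, "women_reproductive_age")
  check_range(span_years, "span_years", lower = 0, open_lower = TRUE)
  tfr * women_reproductive_age / span_years
}

#' Unintended pregnancies from method failure and unmet need
#'
#' Unintended pregnancies arise from two sources:
#' contraceptive users whose method fails, `CU * (1 - e)`, and women with an
#' unmet need for contraception who become pregnant, `UN * rho`.
#'
#' @param cu Number of women using contraception (>= 0).
#' @param effectiveness Mix-weighted average effectiveness in \[0, 1\].
#' @param un Number of women with unmet need (>= 0).
#' @param rho Annual pregnancy rate among women with unmet need (default
#'   0.31).
#' @return A tibble with columns `from_failure`, `from_unmet_need`, and
#'   their sum `total`.
#' @examples
#' unintended_pregnancies(cu = 1000, effectiveness = 0.9, un = 500)
#' @export
unintended_pregnancies <- function(cu, effectiveness, un, rho = 0.31) {
  check_nonnegative(cu, "cu")
  check_proportion(effectiveness, "effectiveness")
  check_nonnegative(un, "un")
  check_proportion(rho, "rho")
  failure <- cu * (1 - effectiveness)
  unmet <- un * rho
  tibble(from_failure = failure, from_unmet_need = unmet,
         total = failure + unmet)
}

#' Induced abortions as a proportion of unintended pregnancies
#'
#' `A = U * alpha`. Expressing abortion as a proportion of unintended
#' pregnancies (rather than an exogenous rate) lets the abortion count
#' respond to changes in contraceptive use and unmet need while `alpha`
#' stays constant.
#'
#' @param u Unintended pregnancies (>= 0).
#' @param alpha Proportion terminated by induced abortion, in \[0, 1\].
#' @return Induced abortions, `<= u`.
#' @examples
#' abortions_from_unintended(480000, 0.58333)
#' @export
abortions_from_unintended <- function(u, alpha) {
  check_nonnegative(u, "u")
  check_proportion(alpha, "alpha")
  u * alpha
}

#' Calibrate the abortion proportion from an observed count
#'
#' `alpha = A / U` at baseline, then held constant across projection years.
#'
#' @param observed_abortions Observed induced abortions (>= 0, <= `u`).
#' @param u Unintended pregnancies in the same year (> 0).
#' @return The abortion proportion `alpha`.
#' @examples
#' calibrate_alpha(280000, 480000)
#' @export
calibrate_alpha <- function(observed_abortions, u) {
  check_nonnegative(observed_abortions, "observed_abortions")
  check_range(u, "u", lower = 0, open_lower = TRUE)
  if (any(observed_abortions > u)) {
    fp_abort(
      paste0("Observed abortions exceed unintended pregnancies; in this ",
             "model every induced abortion terminates an unintended pregnancy."),
      class = "fp_error_inconsistent"
    )
  }
  observed_abortions / u
}

#' Stillbirths from live births
#'
#' `S = B / 1000 * sigma`, with `sigma` in stillbirths per 1000 live births.
#'
#' @param births Live births (>= 0).
#' @param sigma Stillbirth rate per 1000 live births (default 19, the global
#'   average).
#' @return Stillbirths.
#' @examples
#' stillbirths_from_births(732000, sigma = 44)
#' @export
stillbirths_from_births <- function(births, sigma = 19) {
  check_nonnegative(births, "births")
  check_nonnegative(sigma, "sigma")
  births / 1000 * sigma
}

#' Miscarriages from the other pregnancy outcomes
#'
#' `M = (B + A + S) * mu / (1 - mu)`, so that miscarriages make up exactly
#' the proportion `mu` of all pregnancies `P = B + A + M + S`.
#'
#' @param births,abortions,stillbirths Counts of the other outcomes (>= 0).
#' @param mu Miscarriage proportion of pregnancies, in \[0, 1) (default
#'   0.13).
#' @return Miscarriages.
#' @examples
#' miscarriages_from_outcomes(4900000, 1900000, 87000)
#' @export
miscarriages_from_outcomes <- function(births, abortions, stillbirths,
                                       mu = 0.13) {
  check_nonnegative(births, "births")
  check_nonnegative(abortions, "abortions")
  check_nonnegative(stillbirths, "stillbirths")
  check_range(mu, "mu", 0, 1, open_upper = TRUE)
  (births + abortions + stillbirths) * mu / (1 - mu)
}

#' Assemble a pregnancy-outcome record
#'
#' Sums the four outcomes into total pregnancies, `P = B + A + M + S`, and
#' attaches the unintended-pregnancy breakdown. Counts are real-valued;
#' rounding to report granularity happens only in [write_report()].
#'
#' @param births,abortions,miscarriages,stillbirths Outcome counts (>= 0).
#' @param from_failure,from_unmet_need Unintended pregnancies by source
#'   (default 0).
#' @return A tibble of class `"fp_outcomes"` with columns `pregnancies`,
#'   `births`, `abortions`, `miscarriages`, `stillbirths`,
#'   `unintended_total`, `unintended_failure`, `unintended_unmet_need`.
#' @examples
#' assemble_outcomes(732000, 110000, 126100, 32000)
#' @export
assemble_outcomes <- function(births, abortions, miscarriages, stillbirths,
                              from_failure = 0, from_unmet_need = 0) {
  check_nonnegative(births, "births")
  check_nonnegative(abortions, "abortions")
  check_nonnegative(miscarriages, "miscarriages")
  check_nonnegative(stillbirths, "stillbirths")
  check_nonnegative(from_failure, "from_failure")
  check_nonnegative(from_unmet_need, "from_unmet_need")
  out <- tibble(
    pregnancies = births + abortions + miscarriages + stillbirths,
    births = births,
    abortions = abortions,
    miscarriages = miscarriages,
    stillbirths = stillbirths,
    unintended_total = from_failure + from_unmet_need,
    unintended_failure = from_failure,
    unintended_unmet_need = from_unmet_need
  )
  class(out) <- c("fp_outcomes", class(out))
  out
}

#' One-call pregnancy-outcome accounting
#'
#' Chains the outcome equations for a single year: unintended pregnancies
#' from contraceptive users and unmet need, abortions as a constant
#' proportion of unintended pregnancies, stillbirths from births, and
#' miscarriages closing the accounting so that `M / P = mu`.
#'
#' @param births Live births, either supplied directly or computed upstream
#'   via [births_from_tfr()].
#' @param cu Women using contraception.
#' @param un Women with unmet need for contraception.
#' @param effectiveness Average contraceptive effectiveness in \[0, 1\].
#' @param params An [outcome_parameters()] object (holds `mu`, `sigma`,
#'   `rho`, `alpha`).
#' @return A tibble of class `"fp_outcomes"`; see [assemble_outcomes()].
#' @examples
#' pregnancy_outcomes(
#'   births = 732000, cu = 392700, un = 928200, effectiveness = 0.95,
#'   params = outcome_parameters(sigma = 44, alpha = 0.357)
#' )
#' @export
pregnancy_outcomes <- function(births, cu, un, effectiveness, params) {
  stopifnot(inherits(params, "fp_outcome_parameters"))
  u <- unintended_pregnancies(cu, effectiveness, un, rho = params$rho)
  a <- abortions_from_unintended(u$total, params$alpha)
  s <- stillbirths_from_births(births, sigma = params$sigma)
  m <- miscarriages_from_outcomes(births, a, s, mu = params$mu)
  assemble_outcomes(births, a, m, s,
                    from_failure = u$from_failure,
                    from_unmet_need = u$from_unmet_need)
}
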