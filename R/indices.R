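#' Bongaarts fertility-inhibition indices
#'
#' The proximate-determinants framework expresses the total fertility rate
#' (TFR) as a product of five indices acting on total fecundity (TF):
#' `TFR = Cm * Ci * Ca * Cs * Cc * TF`. Each index lies in (0, 1] (the
#' sterility index can slightly exceed 1) and measures the proportion of
#' potential fertility remaining after one inhibiting factor acts.
#'
#' * `index_marriage()` — Cm, the proportion of women 15--49 married or in
#'   union (exposure to pregnancy).
#' * `index_postpartum()` — Ci = 20 / (18.5 + PPI), where PPI is the median
#'   duration of postpartum insusceptibility in months: 20 months is the
#'   birth interval without breastfeeding or postpartum abstinence, 18.5 + PPI
#'   the interval with them.
#' * `index_sterility()` — Cs = (7.63 - 0.11 s) / 7.3, where s is the percent
#'   of women 45--49 who are childless, a regression-based proxy for primary
#'   and secondary sterility.
#' * `index_abortion()` — Ca = TFR / (TFR + 0.4 (1 + CPR) TAR), where TAR is
#'   the total abortion rate (lifetime induced abortions per woman); each
#'   abortion averts about 0.4 births, more when contraceptive use is high.
#'   Conventionally evaluated with the previous year's TFR.
#' * `index_contraception()` — Cc = 1 - 1.08 * CPR * e, where CPR is
#'   contraceptive prevalence among the exposed population and e the
#'   mix-weighted average effectiveness; 1.08 corrects for sterilised women
#'   who would be infecund anyway.
#'
#' All functions are vectorised and validate their domains.
#'
#' @param proportion_married Proportion of women 15--49 married or in union,
#'   in \[0, 1\].
#' @param ppi_months Median postpartum insusceptibility in months (>= 0).
#' @param pct_childless Percent of women 45--49 with no live birth, in
#'   \[0, 100\] and below 69.36 (the numerator must stay positive).
#' @param tfr_prev Total fertility rate entering the abortion index,
#'   normally the previous year's (> 0).
#' @param cpr Contraceptive prevalence rate as a proportion in \[0, 1\].
#' @param tar Total abortion rate: lifetime induced abortions per woman
#'   (>= 0).
#' @param effectiveness Average contraceptive effectiveness as a proportion
#'   in \[0, 1\].
#' @return A numeric vector of index values.
#' @examples
#' index_postpartum(11.7) # long breastfeeding, strong inhibition
#' index_contraception(cpr = 0.58, effectiveness = 0.96)
#' index_abortion(tfr_prev = 6.1, cpr = 0.11, tar = 1.085)
#' @name fertility_indices
NULL

#' @rdname fertility_indices
#' @export
index_marriage <- function(proportion_married) {
  check_range(proportion_married, "proportion_married", 0, 1, open_lower = TRUE)
  proportion_married
}

#' @rdname fertility_indices
#' @export
index_postpartum <- function(ppi_months) {
  check_nonnegative(ppi_months, "ppi_months")
  20 / (18.5 + ppi_months)
}

#' @rdname fertility_indices
#' @export
index_sterility <- function(pct_childless) {
  check_range(pct_childless, "pct_childless", 0, 100)
  num <- 7.63 - 0.11 * pct_childless
  if (any(num <= 0)) {
    fp_abort_input(
      "`pct_childless` must be below 69.36 so the sterility index stays positive."
    )
  }
  num / 7.3
}

#' @rdname fertility_indices
#' @export
index_contraception <- function(cpr, effectiveness) {
  check_proportion(cpr, "cpr")
  check_proportion(effectiveness, "effectiveness")
  cc <- 1 - 1.08 * cpr * effectiveness
  if (any(cc <= 0)) {
    i <- which(cc <= 0)[1]
    fp_abort_domain(sprintf(
      paste0("Contraception index is non-positive: 1.08 * cpr * effectiveness ",
             "must stay below 1 (cpr = %g, effectiveness = %g)."),
      cpr[pmin(i, length(cpr))], effectiveness[pmin(i, length(effectiveness))]
    ))
  }
  cc
}

#' @rdname fertility_indices
#' @export
index_abortion <- function(tfr_prev, cpr, tar) {
  check_range(tfr_prev, "tfr_prev", lower = 0, open_lower = TRUE)
  check_proportion(cpr, "cpr")
  check_nonnegative(tar, "tar")
  tfr_prev / (tfr_prev + 0.4 * (1 + cpr) * tar)
}

#' Convert an annual abortion rate to a total abortion rate
#'
#' Estimates of induced abortion are often reported as abortions per 1000
#' women of reproductive age per year; the abortion index needs the total
#' abortion rate (TAR), the average lifetime abortions per woman. The
#' conversion multiplies the annual per-woman rate by the length of the
#' reproductive span (ages 15--49, 35 years by default).
#'
#' @param rate_per_1000 Annual induced abortions per 1000 women of
#'   reproductive age (>= 0).
#' @param span_years Length of the reproductive span in years (default 35).
#' @return TAR: lifetime abortions per woman.
#' @examples
#' tar_from_abortion_rate(31) # 1.085 abortions per woman over 35 years
#' @export
tar_from_abortion_rate <- function(rate_per_1000, span_years = 35) {
  check_nonnegative(rate_per_1000, "rate_per_1000")
  check_range(span_years, "span_years", lower = 0, open_lower = TRUE)
  rate_per_1000 * span_years / 1000
}

#' Assemble proximate-determinant inputs
#'
#' Builds a tibble of the raw inputs to the five fertility indices for one or
#' more populations/years. All prevalences are proportions in \[0, 1\];
#' percent-scale values in configuration files are converted before reaching
#' this point. `effectiveness` may be given directly or computed from a
#' method mix via [average_effectiveness()]; a directly supplied value takes
#' precedence.
#'
#' @param proportion_married,ppi_months,pct_childless_45_49,cpr,tar See
#'   [fertility_indices].
#' @param effectiveness Average contraceptive effectiveness in \[0, 1\], or
#'   `NULL` to derive it from `method_mix`.
#' @param method_mix Optional method mix (see [average_effectiveness()]).
#' @param tfr_for_ca The TFR used inside the abortion index, normally the
#'   previous year's (> 0).
#' @param failure_rates Failure-rate table used when deriving effectiveness
#'   from `method_mix`.
#' @return A tibble with one row per population and the validated input
#'   columns.
#' @examples
#' proximate_inputs(
#'   proportion_married = 0.85, ppi_months = 11.7, pct_childless_45_49 = 2.2,
#'   cpr = 0.11, effectiveness = 0.95, tar = 1.085, tfr_for_ca = 6.1
#' )
#' @export
proximate_inputs <- function(proportion_married, ppi_months,
                             pct_childless_45_49, cpr,
                             effectiveness = NULL, method_mix = NULL,
                             tar = 0, tfr_for_ca,
                             failure_rates = fp_failure_rates()) {
  if (is.null(effectiveness)) {
    if (is.null(method_mix)) {
      fp_abort_input("Supply either `effectiveness` or `method_mix`.")
    }
    effectiveness <- average_effectiveness(method_mix, failure_rates)
  }
  out <- tibble(
    proportion_married = proportion_married,
    ppi_months = ppi_months,
    pct_childless_45_49 = pct_childless_45_49,
    cpr = cpr,
    effectiveness = effectiveness,
    tar = tar,
    tfr_for_ca = tfr_for_ca
  )
  validate_proximate_inputs(out)
  out
}

# Validates the invariants of a proximate-inputs table; returns it invisibly.
validate_proximate_inputs <- function(inputs) {
  needed <- c("proportion_married", "ppi_months", "pct_childless_45_49",
              "cpr", "effectiveness", "tar", "tfr_for_ca")
  missing <- setdiff(needed, names(inputs))
  if (length(missing) > 0) {
    fp_abort_input(sprintf(
      "Proximate inputs are missing column(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  check_range(inputs$proportion_married, "proportion_married", 0, 1,
              open_lower = TRUE)
  check_nonnegative(inputs$ppi_months, "ppi_months")
  check_range(inputs$pct_childless_45_49, "pct_childless_45_49", 0, 100)
  check_proportion(inputs$cpr, "cpr")
  check_proportion(inputs$effectiveness, "effectiveness")
  check_nonnegative(inputs$tar, "tar")
  check_range(inputs$tfr_for_ca, "tfr_for_ca", lower = 0, open_lower = TRUE)
  if (any(1.08 * inputs$cpr * inputs$effectiveness >= 1)) {
    fp_abort_domain(
      "1.08 * cpr * effectiveness must stay below 1 for the contraception index."
    )
  }
  invisible(inputs)
}

#' Compose the total fertility rate from its proximate determinants
#'
#' Evaluates all five indices on a table of proximate inputs and multiplies
#' them with total fecundity: `TFR = Cm * Ci * Ca * Cs * Cc * TF`.
#'
#' @param inputs A proximate-inputs tibble from [proximate_inputs()] (or any
#'   data frame with the same columns).
#' @param tf Total fecundity: births per woman absent all inhibiting factors
#'   (> 0). Bongaarts places plausible values around 13--18.
#' @return The input tibble with columns `cm`, `ci`, `ca`, `cs`, `cc`, `tf`
#'   and `tfr` appended; class `"fp_indices"`.
#' @examples
#' inp <- proximate_inputs(0.85, 11.7, 2.2, cpr = 0.11, effectiveness = 0.95,
#'                         tar = 1.085, tfr_for_ca = 6.1)
#' compose_tfr(inp, tf = 13)
#' @export
compose_tfr <- function(inputs, tf) {
  validate_proximate_inputs(inputs)
  check_range(tf, "tf", lower = 0, open_lower = TRUE)
  out <- dplyr::mutate(
    as_tibble(inputs),
    cm = index_marriage(.data$proportion_married),
    ci = index_postpartum(.data$ppi_months),
    ca = index_abortion(.data$tfr_for_ca, .data$cpr, .data$tar),
    cs = index_sterility(.data$pct_childless_45_49),
    cc = index_contraception(.data$cpr, .data$effectiveness),
    tf = tf,
    tfr = .data$cm * .data$ci * .data$ca * .data$cs * .data$cc * tf
  )
  class(out) <- c("fp_indices", class(out))
  out
}

#' Calibrate total fecundity from an observed fertility rate
#'
#' Rearranges the proximate-determinants identity to solve for total
#' fecundity: `TF = TFR / (Cm * Ci * Cs * Ca * Cc)`. TF is assumed constant
#' over time, so a single baseline calibration anchors all projection years.
#' At baseline the abortion index's TFR circularity is resolved as a fixed
#' point: `tfr_for_ca` in `inputs` should equal the observed TFR.
#'
#' A warning (class `"fp_warning_tf_band"`) is emitted when the calibrated TF
#' falls outside Bongaarts' plausible band of about 13--18; empirical
#' applications do produce values well outside it, so this is not an error.
#'
#' @param inputs A proximate-inputs tibble (single row).
#' @param observed_tfr The observed total fertility rate (> 0).
#' @return Total fecundity (births per woman) such that
#'   `compose_tfr(inputs, TF)$tfr` reproduces `observed_tfr` to within 1e-9
#'   relative.
#' @examples
#' inp <- proximate_inputs(0.85, 11.7, 2.2, cpr = 0.11, effectiveness = 0.95,
#'                         tar = 1.085, tfr_for_ca = 6.1)
#' calibrate_total_fecundity(inp, observed_tfr = 6.1)
#' @export
calibrate_total_fecundity <- function(inputs, observed_tfr) {
  check_range(observed_tfr, "observed_tfr", lower = 0, open_lower = TRUE)
  validate_proximate_inputs(inputs)
  idx <- compose_tfr(inputs, tf = 1)
  prod_indices <- idx$cm * idx$ci * idx$ca * idx$cs * idx$cc
  if (any(prod_indices == 0)) {
    fp_abort_domain(
      "Calibration is degenerate: at least one fertility index is zero."
    )
  }
  tf <- observed_tfr / prod_indices
  out_of_band <- tf < 13 | tf > 18
  if (any(out_of_band)) {
    warn(
      sprintf(
        paste0("Calibrated total fecundity %s lies outside the plausible ",
               "13-18 band; inputs or the observed TFR may be inconsistent."),
        paste(format(tf[out_of_band], digits = 4), collapse = ", ")
      ),
      class = "fp_warning_tf_band"
    )
  }
  tf
}
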