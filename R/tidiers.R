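#' Tidy a baseline calibration
#'
#' Returns one row per model quantity fixed at calibration: the five
#' fertility indices at baseline, total fecundity, the abortion proportion,
#' and average effectiveness.
#'
#' @param x An `fp_calibration`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `value`, `description`.
#' @method tidy fp_calibration
#' @export
tidy.fp_calibration <- function(x, ...) {
  idx <- compose_tfr(x$inputs, tf = x$tf)
  tibble(
    term = c("cm", "ci", "ca", "cs", "cc", "tf", "alpha", "effectiveness"),
    value = c(idx$cm, idx$ci, idx$ca, idx$cs, idx$cc, x$tf, x$alpha,
              x$effectiveness),
    description = c(
      "marriage index", "postpartum insusceptibility index",
      "abortion index", "sterility index", "contraception index",
      "total fecundity (births/woman)",
      "abortions / unintended pregnancies",
      "mix-weighted contraceptive effectiveness"
    )
  )
}

#' Summarise a baseline calibration in one row
#'
#' @param x An `fp_calibration`.
#' @param ... Unused.
#' @return A one-row tibble: preset, baseline year, observed TFR, recomposed
#'   TFR, total fecundity, alpha, effectiveness.
#' @method glance fp_calibration
#' @export
glance.fp_calibration <- function(x, ...) {
  idx <- compose_tfr(x$inputs, tf = x$tf)
  tibble(
    preset = x$preset_name,
    baseline_year = x$baseline_year,
    observed_tfr = x$observed_tfr,
    recomposed_tfr = idx$tfr,
    tf = x$tf,
    alpha = x$alpha,
    effectiveness = x$effectiveness
  )
}

#' Tidy a projection series
#'
#' Pivots the outcome counts to long form, one row per year and outcome, the
#' shape ggplot2 and summary pipelines expect.
#'
#' @param x An `fp_projection`.
#' @param ... Unused.
#' @return A tibble with columns `year`, `outcome`, `count`.
#' @method tidy fp_projection
#' @export
tidy.fp_projection <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[, c("year", "pregnancies", "births", "abortions",
                     "miscarriages", "stillbirths", "unintended_total")],
    -"year", names_to = "outcome", values_to = "count"
  )
}

#' Plot a projection series
#'
#' Line plot of outcome counts over the projection years.
#'
#' @param object An `fp_projection`.
#' @param outcomes Outcome columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fp_projection
#' @export
autoplot.fp_projection <- function(object,
                                   outcomes = c("pregnancies", "births",
                                                "abortions", "stillbirths"),
                                   ...) {
  long <- tidy(object)
  long <- long[long$outcome %in% outcomes, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$count,
                                     colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = scales_comma) +
    ggplot2::labs(
      title = sprintf("%s — %s", attr(object, "preset_name"),
                      attr(object, "scenario_name")),
      x = "Year", y = "Count", colour = "Outcome"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a scenario comparison
#'
#' Per-year differences (scenario b minus scenario a) in the outcome
#' counts.
#'
#' @param object An `fp_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fp_comparison
#' @export
autoplot.fp_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("year", "d_births", "d_abortions",
                          "d_pregnancies", "d_stillbirths")],
    -"year", names_to = "outcome", values_to = "difference"
  )
  long$outcome <- sub("^d_", "", long$outcome)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$difference,
                                     colour = .data$outcome)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(labels = scales_comma) +
    ggplot2::labs(
      title = sprintf("%s minus %s", attr(object, "scenario_b"),
                      attr(object, "scenario_a")),
      x = "Year", y = "Difference in count", colour = "Outcome"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the fertility-inhibition indices of a calibration
#'
#' Bar chart of the five indices at baseline; the distance of each bar
#' below 1 shows how much that determinant inhibits fertility.
#'
#' @param object An `fp_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fp_calibration
#' @export
autoplot.fp_calibration <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term %in% c("cm", "ci", "ca", "cs", "cc"), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(
      title = sprintf("Fertility-inhibition indices: %s", object$preset_name),
      x = "Index", y = "Value"
    ) +
    ggplot2::theme_minimal()
}

# Thousands-separator label formatter (avoids depending on scales directly).
scales_comma <- function(x) format(x, big.mark = ",", scientific = FALSE)
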