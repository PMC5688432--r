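#' Contraceptive method failure rates
#'
#' Annual failure rates by contraceptive method: the proportion of women
#' using a method who become pregnant within a year despite use. The bundled
#' default table carries the nine standard methods used by the Spectrum
#' family-planning module (Cleland's developing-country estimates and
#' Trussell's United States estimates). Effectiveness of a method is the
#' complement of its failure rate.
#'
#' A custom table can be supplied as a two-column CSV with columns
#' `method` and `failure_rate_percent` (0--100). Rates are converted to
#' proportions on read.
#'
#' @param path Path to a CSV of failure rates. `NULL` (default) loads the
#'   bundled table.
#' @return A tibble with columns `method` (character) and `failure_rate`
#'   (annual failure probability as a proportion in \[0, 1\]).
#' @examples
#' fp_failure_rates()
#' @export
fp_failure_rates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "failure_rates.csv", package = "famplanr")
  }
  if (!file.exists(path)) {
    fp_abort_config(sprintf("Failure-rate file not found: '%s'.", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    method = readr::col_character(),
    failure_rate_percent = readr::col_double()
  ))
  if (!identical(names(raw), c("method", "failure_rate_percent"))) {
    fp_abort_config(
      "Failure-rate CSV must have columns 'method' and 'failure_rate_percent'."
    )
  }
  check_range(raw$failure_rate_percent, "failure_rate_percent", 0, 100)
  if (anyDuplicated(raw$method)) {
    fp_abort_config("Failure-rate CSV lists a method more than once.")
  }
  tibble(method = raw$method, failure_rate = raw$failure_rate_percent / 100)
}

#' Mix-weighted average contraceptive effectiveness
#'
#' Averages per-method effectiveness (one minus the annual failure rate)
#' weighted by the proportion of contraceptive users relying on each method:
#' `e = 1 - sum_m mix_m * failure_m`.
#'
#' @param mix A method mix: either a named numeric vector of user proportions
#'   or a data frame with columns `method` and `proportion`. Proportions must
#'   sum to 1.
#' @param rates A failure-rate table as returned by [fp_failure_rates()].
#' @return Average effectiveness as a proportion in \[0, 1\].
#' @examples
#' average_effectiveness(c("Oral pill" = 0.5, "Male condom" = 0.5))
#' @export
average_effectiveness <- function(mix, rates = fp_failure_rates()) {
  mix <- as_method_mix(mix)
  unknown <- setdiff(mix$method, rates$method)
  if (length(unknown) > 0) {
    fp_abort_lookup(sprintf(
      "Unknown method(s): %s. Valid methods: %s.",
      paste(sQuote(unknown), collapse = ", "),
      paste(sQuote(rates$method), collapse = ", ")
    ))
  }
  joined <- dplyr::left_join(mix, rates, by = "method")
  1 - sum(joined$proportion * joined$failure_rate)
}

# Normalise a method mix to tibble(method, proportion) and validate it.
as_method_mix <- function(mix) {
  if (is.numeric(mix) && !is.null(names(mix))) {
    mix <- tibble(method = names(mix), proportion = unname(mix))
  } else if (is.data.frame(mix)) {
    if (!all(c("method", "proportion") %in% names(mix))) {
      fp_abort_input("A method-mix data frame needs columns 'method' and 'proportion'.")
    }
    mix <- tibble(method = as.character(mix$method), proportion = mix$proportion)
  } else {
    fp_abort_input("`mix` must be a named numeric vector or a data frame.")
  }
  check_proportion(mix$proportion, "proportion")
  if (abs(sum(mix$proportion) - 1) > 1e-9) {
    fp_abort_input(sprintf(
      "Method-mix proportions must sum to 1 (got %.12f).", sum(mix$proportion)
    ))
  }
  if (anyDuplicated(mix$method)) {
    fp_abort_input("Method mix lists a method more than once.")
  }
  mix
}
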