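#' Write a projection report to CSV
#'
#' Writes the per-year outcome table with columns `year`, `pregnancies`,
#' `births`, `abortions`, `miscarriages`, `stillbirths`,
#' `unintended_total`, `unintended_failure`, `unintended_unmet_need`.
#' Counts are real-valued throughout the model; rounding to a report
#' granularity (e.g. the nearest 100, matching the coarseness of published
#' country tables) happens only here. A companion metadata file
#' (`<path stem>_meta.csv`) records the calibrated total fecundity, abortion
#' proportion, and the per-year effectiveness so a report is traceable to
#' its calibration.
#'
#' @param series An `fp_projection` from [project()].
#' @param path Output CSV path.
#' @param rounding Round counts to the nearest multiple of this value;
#'   `NULL` (default) writes unrounded values.
#' @return `path`, invisibly. The metadata path is attached as attribute
#'   `"meta_path"`.
#' @examples
#' cal <- calibrate_baseline(load_preset("Mali"))
#' proj <- project(cal, scenario("constant", c(2015, 2025)))
#' out <- tempfile(fileext = ".csv")
#' write_report(proj, out, rounding = 100)
#' @export
write_report <- function(series, path, rounding = NULL) {
  stopifnot(inherits(series, "fp_projection"))
  if (nrow(series) == 0) {
    fp_abort_input("Cannot write a report for an empty projection series.")
  }
  cols <- c("year", "pregnancies", "births", "abortions", "miscarriages",
            "stillbirths", "unintended_total", "unintended_failure",
            "unintended_unmet_need")
  out <- as_tibble(series)[, cols]
  if (!is.null(rounding)) {
    check_range(rounding, "rounding", lower = 1)
    out <- dplyr::mutate(
      out,
      dplyr::across(-"year", ~ round(.x / rounding) * rounding)
    )
  }
  readr::write_csv(out, path)

  meta_path <- paste0(sub("\\.csv$", "", path), "_meta.csv")
  meta <- tibble(
    year = series$year,
    preset = attr(series, "preset_name") %||% NA_character_,
    scenario = attr(series, "scenario_name") %||% NA_character_,
    total_fecundity = attr(series, "tf"),
    alpha = attr(series, "alpha"),
    effectiveness = series$effectiveness
  )
  readr::write_csv(meta, meta_path)
  invisible(structure(path, meta_path = meta_path))
}

#' Read a projection report written by [write_report()]
#'
#' @param path CSV path.
#' @return A tibble with the report columns.
#' @export
read_report <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_double(), .default = readr::col_double()
  ))
}
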