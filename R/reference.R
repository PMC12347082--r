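# Published summary statistics of the 26-patient reference cohort on
# which the synthetic generator's defaults are patterned. Shipped as
# plain-text CSVs under inst/extdata/.

#' Reference cohort summary statistics
#'
#' Per segment and parameter: the published mean T0 -> T1 planning
#' difference, its SEM, the top-10% absolute value, the printed 95%
#' confidence interval bounds, and the printed p-value of the one-sample
#' t-test, for the 26-patient reference cohort. Rotations in degrees,
#' translations in mm. These printed values seed the synthetic
#' generator's defaults and serve as inputs to the summary-reconstruction
#' checks.
#'
#' @return A data.frame with columns `segment`, `parameter`, `mean`,
#'   `sem`, `top10_value`, `ci_low`, `ci_high`, `p_printed`.
#' @export
reference_cohort_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_cohort_summary.csv",
                              package = "gnathodiff"),
                  stringsAsFactors = FALSE)
}

#' Reference out-of-range percentages
#'
#' Published percentage of reference-cohort patients whose absolute
#' planning difference exceeded the clinical tolerances (2 mm for
#' translations, 4 degrees for rotations), per segment and parameter,
#' including the per-segment `mean_rotations` / `mean_translations`
#' summary rows.
#'
#' @return A data.frame with columns `parameter`, `dental_maxilla`,
#'   `dental_mandible`, `bony_mandible`.
#' @export
reference_out_of_range <- function() {
  utils::read.csv(system.file("extdata", "reference_out_of_range.csv",
                              package = "gnathodiff"),
                  stringsAsFactors = FALSE)
}
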