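#' Published five-year stroke case-study coefficients
#'
#' Age-stratified single-variable logistic regression results from a
#' published case study of five-year first-ischemic-stroke risk on
#' Framingham Heart Study clinical exams: for each of the seven risk
#' factors and the four age groups (under 50, 50 to 59, 60 to 69, 70 plus),
#' the fitted coefficient, Wald standard error, and p-value. The underlying
#' individual-level data are request-only, so this summary table is
#' distributed with the package to drive steps 2 and 3 of the framework
#' directly.
#'
#' Two p-values were published only as an upper bound ("< 2e-16") and are
#' stored at that bound; they enter the framework solely through
#' significant/not-significant flags, which the bound determines.
#'
#' @return A `stratified_fits` data frame (28 rows) as produced by
#'   [fit_stratified()], with `converged = TRUE` throughout and no sample
#'   sizes (not published).
#' @export
#' @examples
#' fits <- stroke_case_study()
#' compare_factors(fits)
stroke_case_study <- function() {
  path <- system.file("extdata", "stroke_case_study_fits.csv",
                      package = "ageprop")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$n <- NA_integer_
  df$n_events <- NA_integer_
  df$converged <- TRUE
  df$center <- NA_real_
  df$scale <- NA_real_
  structure(df, scaling = "published", groups = age_groups(),
            class = c("stratified_fits", "data.frame"))
}
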