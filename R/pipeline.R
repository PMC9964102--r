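#' Framework configuration
#'
#' Collects every tunable of the three-step framework in one object: the
#' age partition, the prediction window, the matched-design parameters, the
#' significance levels, the predictor scaling and the proportionality
#' level.
#'
#' @param cut_points age-group cut points in years (default
#'   `c(50, 60, 70)`, i.e., under 50 / 50-59 / 60-69 / 70 plus).
#' @param window_years prediction window (default 5).
#' @param match_ratio controls per case (default 2).
#' @param age_caliper,max_caliper matching calipers, see [match_config()].
#' @param levels magnitude-test significance levels, strong first.
#' @param pattern_level significance-pattern level.
#' @param scaling continuous-predictor scaling for [fit_stratified()].
#' @param proportionality_level lack-of-fit level for step 3.
#' @param age_coordinates optional named overrides for open-ended group
#'   coordinates, e.g., `c("under 50" = 44.5, "70 plus" = 76)`.
#' @param seed RNG seed for the matching draw.
#' @return An object of class `framework_config`.
#' @export
framework_config <- function(cut_points = c(50, 60, 70), window_years = 5,
                             match_ratio = 2L, age_caliper = 0,
                             max_caliper = 3, levels = c(0.05, 0.10),
                             pattern_level = 0.05, scaling = "pooled",
                             proportionality_level = 0.05,
                             age_coordinates = NULL, seed = NULL) {
  stopifnot(all(levels > 0), all(levels < 1), window_years > 0)
  structure(list(cut_points = cut_points, window_years = window_years,
                 match_ratio = as.integer(match_ratio),
                 age_caliper = age_caliper, max_caliper = max_caliper,
                 levels = levels, pattern_level = pattern_level,
                 scaling = scaling,
                 proportionality_level = proportionality_level,
                 age_coordinates = age_coordinates, seed = seed),
            class = "framework_config")
}

#' Run the full framework end to end
#'
#' Orchestrates the three steps on either a raw exam cohort (flag outcomes
#' -> missing-data rules -> 1:2 matched design -> stratified fits) or a
#' pre-computed fit table such as [stroke_case_study()] (steps 2-3 only).
#' Factors whose step-2 verdict is "stop" are excluded from step 3; when
#' every factor stops, the step-3 block is empty and the manifest records
#' that.
#'
#' @param cohort an exam-level cohort `data.frame`, or `NULL`.
#' @param fits a `stratified_fits` table (used instead of steps 0-1), or
#'   `NULL`.
#' @param config a [framework_config()].
#' @param factors risk-factor specifications (cohort route only).
#' @return An object of class `framework_run`: `fits`, `step2`
#'   (see [compare_factors()]), `step3` (see [assess_proportionality()]),
#'   `design` (the matched design set, cohort route only), and a `manifest`
#'   list (configuration, seed, package version, stages run) sufficient to
#'   re-execute the run.
#' @export
run_framework <- function(cohort = NULL, fits = NULL,
                          config = framework_config(),
                          factors = default_risk_factors()) {
  stopifnot(inherits(config, "framework_config"))
  if (is.null(cohort) == is.null(fits))
    stop("supply exactly one of `cohort` or `fits`")
  groups <- age_groups(config$cut_points)
  stages <- character(0)
  design <- NULL
  if (!is.null(cohort)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    if ("exam_time" %in% names(cohort)) {
      cohort <- flag_outcomes(cohort, config$window_years)
      stages <- c(stages, "flag_outcomes")
    }
    cohort <- apply_missingness_rules(cohort, factors, verbose = FALSE)
    stages <- c(stages, "missingness_rules")
    design <- select_matched_controls(
      cohort,
      match_config(ratio = config$match_ratio,
                   age_caliper = config$age_caliper,
                   max_caliper = config$max_caliper),
      groups)
    stages <- c(stages, "matched_design")
    fits <- fit_stratified(design, factors, groups, scaling = config$scaling)
    stages <- c(stages, "stratified_fit")
  }
  step2 <- compare_factors(fits, config$levels, config$pattern_level)
  stages <- c(stages, "coefficient_comparison")
  proceed <- names(Filter(function(v) v$proceed_to_step3, step2$verdicts))
  step3 <- NULL
  step3_skipped <- character(0)
  if (length(proceed)) {
    ok <- character(0)
    for (f in proceed) {
      test <- tryCatch({
        pts <- proportionality_points(fits[fits$factor == f, , drop = FALSE],
                                      groups, cohort = design,
                                      age_coordinates = config$age_coordinates)
        nrow(pts) >= 2L
      }, error = function(e) FALSE)
      if (test) ok <- c(ok, f) else step3_skipped <- c(step3_skipped, f)
    }
    if (length(ok)) {
      step3 <- assess_proportionality(
        fits, groups, cohort = design,
        age_coordinates = config$age_coordinates,
        level = config$proportionality_level, factors = ok)
      stages <- c(stages, "proportionality")
    }
  }
  manifest <- list(
    package = "ageprop",
    version = as.character(utils::packageVersion("ageprop")),
    config = unclass(config),
    stages = stages,
    factors_to_step3 = proceed,
    step3_skipped_no_coordinates = step3_skipped)
  structure(list(fits = fits, design = design, step2 = step2, step3 = step3,
                 manifest = manifest),
            class = "framework_run")
}

#' @export
print.framework_run <- function(x, ...) {
  cat("== Age-proportionality framework run ==\n")
  cat(sprintf("stages: %s\n", paste(x$manifest$stages, collapse = " -> ")))
  print(x$step2)
  if (!is.null(x$step3)) print(x$step3)
  else cat("step 3: no factor proceeded (or no age coordinates available)\n")
  invisible(x)
}

#' Write a framework run to disk as CSV/JSON artifacts
#'
#' Emits the fit table (long and wide), the step-2 comparison summary and
#' rule traces, the step-3 summary, the proportionality plot, and a JSON
#' manifest, into `dir`.
#'
#' @param run a [run_framework()] result.
#' @param dir output directory (created if needed).
#' @param plot_format `"png"` or `"svg"`.
#' @return `dir`, invisibly.
#' @export
write_framework_bundle <- function(run, dir, plot_format = c("png", "svg")) {
  stopifnot(inherits(run, "framework_run"))
  plot_format <- match.arg(plot_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(run$fits), file.path(dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(fits_wide_table(run$fits),
                   file.path(dir, "fits_wide.csv"), row.names = FALSE)
  utils::write.csv(run$step2$summary, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  traces <- unlist(lapply(run$step2$comparisons, function(cmp)
    c(paste0("== ", cmp$factor, " =="), cmp$rule_trace)))
  writeLines(traces, file.path(dir, "rule_trace.txt"))
  jsonlite::write_json(
    list(comparisons = run$step2$summary,
         verdicts = lapply(run$step2$verdicts, unclass)),
    file.path(dir, "comparisons.json"), auto_unbox = TRUE, digits = 10)
  if (!is.null(run$step3)) {
    utils::write.csv(run$step3$summary,
                     file.path(dir, "proportionality.csv"), row.names = FALSE)
    jsonlite::write_json(run$step3$summary,
                         file.path(dir, "proportionality.json"),
                         auto_unbox = TRUE, digits = 10)
    plot_proportionality(run$step3,
                         file.path(dir, paste0("proportionality.",
                                               plot_format)))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       force = TRUE)
  invisible(dir)
}
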