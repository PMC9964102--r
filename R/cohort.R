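#' @keywords internal
abort_schema <- function(msg) {
  stop(errorCondition(msg, class = c("ageprop_schema_error", "error", "condition")))
}

#' Describe one modelled risk factor
#'
#' A risk-factor specification names an exam-level column and records whether
#' it is continuous (e.g., systolic blood pressure in mmHg) or categorical
#' (a 0/1 condition or treatment indicator). The kind drives both the
#' missing-data rule (continuous: drop the exam; categorical: recode to the
#' reference level, i.e., "does not have the condition") and whether the
#' predictor is standardized before model fitting.
#'
#' @param name column name in the cohort, e.g., `"systolic_bp"`.
#' @param kind `"continuous"` or `"categorical"`.
#' @param reference_level value coded as the reference (categorical only);
#'   missing categorical values are recoded to this level. Default 0.
#' @return An object of class `risk_factor_spec`.
#' @seealso [default_risk_factors()]
#' @export
#' @examples
#' risk_factor_spec("bmi", "continuous")
risk_factor_spec <- function(name, kind = c("continuous", "categorical"),
                             reference_level = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind)
  structure(list(name = name, kind = kind, reference_level = reference_level),
            class = "risk_factor_spec")
}

#' @export
print.risk_factor_spec <- function(x, ...) {
  cat(sprintf("<risk factor> %s (%s)\n", x$name, x$kind))
  invisible(x)
}

#' The seven stroke risk factors of the default configuration
#'
#' Four continuous factors (systolic blood pressure, diastolic blood
#' pressure, total cholesterol, BMI) and three categorical factors (sex with
#' male as the reference, atrial fibrillation, treatment for high blood
#' pressure).
#'
#' @return A named list of [risk_factor_spec()] objects.
#' @export
default_risk_factors <- function() {
  specs <- list(
    risk_factor_spec("systolic_bp", "continuous"),
    risk_factor_spec("diastolic_bp", "continuous"),
    risk_factor_spec("total_cholesterol", "continuous"),
    risk_factor_spec("bmi", "continuous"),
    risk_factor_spec("sex", "categorical"),
    risk_factor_spec("atrial_fibrillation", "categorical"),
    risk_factor_spec("hbp_treatment", "categorical")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Human-readable display names used in reports and plots
#' @keywords internal
factor_display_names <- function() {
  c(systolic_bp = "Systolic Blood Pressure",
    diastolic_bp = "Diastolic Blood Pressure",
    total_cholesterol = "Total Cholesterol",
    bmi = "BMI",
    sex = "Sex",
    atrial_fibrillation = "Atrial Fibrillation",
    hbp_treatment = "High Blood Pressure Treatment")
}

# Convert a time column to decimal years. Numeric input is passed through;
# Date or ISO "YYYY-MM-DD" strings are converted on the Gregorian mean year.
to_decimal_years <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "Date")) return(1970 + as.numeric(x) / 365.2425)
  if (is.character(x)) {
    num <- suppressWarnings(as.numeric(x))
    looks_date <- grepl("^\\s*\\d{4}-\\d{2}-\\d{2}\\s*$", x)
    if (any(looks_date, na.rm = TRUE)) {
      d <- as.Date(x, format = "%Y-%m-%d")
      conv <- 1970 + as.numeric(d) / 365.2425
      num[looks_date & !is.na(conv)] <- conv[looks_date & !is.na(conv)]
    }
    return(num)
  }
  as.numeric(x)
}

cohort_numeric_columns <- function() {
  c("age", "systolic_bp", "diastolic_bp", "total_cholesterol", "bmi",
    "sex", "atrial_fibrillation", "hbp_treatment", "cvd_status",
    "stroke_within_window")
}

#' Read an exam-level cohort from CSV
#'
#' One row per clinical exam. Required columns are `subject_id`, `age`, and
#' either a pre-computed `stroke_within_window` outcome flag or the pair
#' `exam_time`/`first_stroke_time` from which [flag_outcomes()] can derive it.
#' Time columns may be decimal years or ISO dates (converted to decimal
#' years). Unparseable numeric cells become `NA` rather than errors so that
#' the missing-data rules of [apply_missingness_rules()] can act on them.
#'
#' @param path path to a CSV file.
#' @param factors list of [risk_factor_spec()]; defaults to the seven-factor
#'   configuration.
#' @return A `data.frame` with one row per exam, row order preserved.
#' @export
read_cohort <- function(path, factors = default_risk_factors()) {
  if (!file.exists(path)) abort_schema(sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = TRUE)
  if (nrow(df) == 0L) abort_schema(sprintf("cohort file is empty: %s", path))
  for (col in c("subject_id", "age")) {
    if (!col %in% names(df))
      abort_schema(sprintf("missing required column: %s", col))
  }
  if (!("stroke_within_window" %in% names(df)) &&
      !all(c("exam_time", "first_stroke_time") %in% names(df))) {
    abort_schema(paste("missing required column: stroke_within_window",
                       "(or exam_time + first_stroke_time)"))
  }
  for (col in intersect(cohort_numeric_columns(), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in intersect(c("exam_time", "first_stroke_time"), names(df))) {
    df[[col]] <- to_decimal_years(df[[col]])
  }
  if (any(df$age < 0, na.rm = TRUE)) abort_schema("negative age in cohort")
  df
}

#' Write an exam-level cohort to CSV
#'
#' Inverse of [read_cohort()]: writes the same dialect (missing cells as
#' empty strings) so that a write/read round trip is record-identical.
#'
#' @param cohort cohort `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Flag strokes occurring within the prediction window
#'
#' Sets `stroke_within_window = 1` for exams where the subject's first stroke
#' occurred strictly after the exam and at most `window_years` later, i.e.,
#' the stroke time lies in `(exam_time, exam_time + window_years]`. Exams at
#' or after a subject's first stroke are removed, because the framework
#' concerns the risk of a *first* ischemic stroke. The operation is
#' idempotent.
#'
#' @param cohort cohort `data.frame` with `exam_time` (and, for subjects who
#'   ever stroked, `first_stroke_time`) in decimal years.
#' @param window_years length of the prediction window in years (default 5).
#' @return The cohort with `stroke_within_window` recomputed and post-stroke
#'   exams removed.
#' @export
flag_outcomes <- function(cohort, window_years = 5) {
  if (!is.numeric(window_years) || length(window_years) != 1L || window_years < 0)
    stop("window_years must be a single non-negative number")
  if (!"exam_time" %in% names(cohort))
    abort_schema("missing required column: exam_time")
  fst <- if ("first_stroke_time" %in% names(cohort))
    to_decimal_years(cohort$first_stroke_time) else rep(NA_real_, nrow(cohort))
  et <- to_decimal_years(cohort$exam_time)
  keep <- is.na(fst) | et < fst
  out <- cohort[keep, , drop = FALSE]
  dt <- fst[keep] - et[keep]
  out$stroke_within_window <-
    as.integer(!is.na(dt) & dt > 0 & dt <= window_years)
  rownames(out) <- NULL
  out
}

#' Apply the missing-data rules
#'
#' Exams missing any continuous risk factor are dropped; a missing
#' categorical factor (and missing `cvd_status`, likewise a condition
#' indicator) is recoded to its reference level — a missing condition is
#' treated as not having the condition. Non-missing values are never
#' altered. A summary of drop/recode counts is attached as the
#' `"missingness_summary"` attribute and reported via `message()`.
#'
#' @param cohort cohort `data.frame`.
#' @param factors list of [risk_factor_spec()] covering all modelled factors.
#' @param verbose emit a `message()` summary (default `TRUE`).
#' @return The filtered/recoded cohort.
#' @export
apply_missingness_rules <- function(cohort, factors = default_risk_factors(),
                                    verbose = TRUE) {
  cont <- vapply(factors, function(f) f$kind == "continuous", logical(1))
  cont_names <- intersect(vapply(factors[cont], `[[`, character(1), "name"),
                          names(cohort))
  cat_specs <- factors[!cont]
  drop <- rep(FALSE, nrow(cohort))
  for (col in cont_names) drop <- drop | is.na(cohort[[col]])
  out <- cohort[!drop, , drop = FALSE]
  recoded <- integer(0)
  for (f in cat_specs) {
    if (!f$name %in% names(out)) next
    miss <- is.na(out[[f$name]])
    out[[f$name]][miss] <- f$reference_level
    recoded[f$name] <- sum(miss)
  }
  if ("cvd_status" %in% names(out)) {
    miss <- is.na(out$cvd_status)
    out$cvd_status[miss] <- 0
    recoded["cvd_status"] <- sum(miss)
  }
  summary <- list(n_input = nrow(cohort), n_dropped = sum(drop),
                  n_recoded = recoded)
  attr(out, "missingness_summary") <- summary
  if (verbose) {
    message(sprintf(
      "missingness rules: dropped %d of %d exams (missing continuous factor); recoded %d categorical cells to reference",
      summary$n_dropped, summary$n_input, sum(recoded)))
  }
  rownames(out) <- NULL
  out
}
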