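#' Configuration for matched control selection
#'
#' @param ratio controls per case (default 2, the 1:2 stroke:non-stroke
#'   design).
#' @param age_caliper initial allowed absolute age difference in years
#'   (default 0, i.e., same recorded age).
#' @param max_caliper largest caliper reached by stepwise widening in 1-year
#'   increments when a case has too few exact-age controls (default 3).
#' @param match_on covariates that must agree between a case and its
#'   controls; any subset of `c("age", "cvd_status")`. Age agreement is
#'   governed by the caliper.
#' @param exclude_same_subject disallow a subject's other exams as controls
#'   for their own case exam (default `TRUE`).
#' @param strict error (rather than warn) when a case cannot be fully
#'   matched at the maximum caliper.
#' @param seed optional RNG seed; the control draw is uniform given the seed.
#' @return An object of class `match_config`.
#' @export
match_config <- function(ratio = 2L, age_caliper = 0, max_caliper = 3,
                         match_on = c("age", "cvd_status"),
                         exclude_same_subject = TRUE, strict = FALSE,
                         seed = NULL) {
  stopifnot(ratio >= 1L, age_caliper >= 0, max_caliper >= age_caliper)
  structure(list(ratio = as.integer(ratio), age_caliper = age_caliper,
                 max_caliper = max_caliper, match_on = match_on,
                 exclude_same_subject = isTRUE(exclude_same_subject),
                 strict = isTRUE(strict), seed = seed),
            class = "match_config")
}

#' Build the matched case-control design set
#'
#' Keeps every case exam (`stroke_within_window == 1`) and samples, per case,
#' `ratio` control exams without replacement from the eligible pool: same
#' CVD status (if matched on), age within the caliper, same age group, and —
#' by default — a different subject. Cases are processed in a fixed order
#' (sorted by `subject_id`, then `exam_time`) so the greedy
#' without-replacement draw is reproducible given the seed. When a case has
#' fewer than `ratio` eligible controls at the starting caliper, the caliper
#' is widened in 1-year steps up to `max_caliper`; remaining shortfalls are
#' warned about (or are an error under `strict = TRUE`) and the case is
#' retained with fewer controls.
#'
#' The per-case match report (caliper used, controls found, shortfall) is
#' attached as the `"match_report"` attribute.
#'
#' @param cohort cohort `data.frame` with outcome flags already set.
#' @param config a [match_config()].
#' @param groups an [age_groups()] object; controls must fall in the same
#'   age group as their case so the case:control ratio is maintained within
#'   groups.
#' @return The design-set cohort (cases plus selected controls, original row
#'   order), with a `"match_report"` attribute.
#' @export
select_matched_controls <- function(cohort, config = match_config(),
                                    groups = age_groups()) {
  stopifnot(inherits(config, "match_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!"stroke_within_window" %in% names(cohort))
    abort_schema("missing required column: stroke_within_window")
  case_idx <- which(cohort$stroke_within_window == 1)
  if (!length(case_idx)) stop("cohort contains no cases")
  ctrl_idx <- which(cohort$stroke_within_window == 0)
  grp <- assign_age_group(cohort$age, groups)
  age <- cohort$age
  cvd <- if ("cvd_status" %in% names(cohort)) cohort$cvd_status else
    rep(0, nrow(cohort))
  subj <- as.character(cohort$subject_id)
  et <- if ("exam_time" %in% names(cohort)) to_decimal_years(cohort$exam_time)
        else rep(0, length(case_idx))

  ord <- order(subj[case_idx],
               if (length(et) == nrow(cohort)) et[case_idx] else et)
  case_idx <- case_idx[ord]

  used <- logical(nrow(cohort))
  selected <- integer(0)
  report <- vector("list", length(case_idx))
  match_cvd <- "cvd_status" %in% config$match_on
  match_age <- "age" %in% config$match_on

  for (ci in seq_along(case_idx)) {
    i <- case_idx[ci]
    elig <- integer(0)
    caliper_used <- NA_real_
    for (cal in seq(config$age_caliper, config$max_caliper, by = 1)) {
      ok <- !used[ctrl_idx]
      if (match_age) ok <- ok & abs(age[ctrl_idx] - age[i]) <= cal
      ok <- ok & (as.integer(grp[ctrl_idx]) == as.integer(grp[i]))
      if (match_cvd) ok <- ok & (cvd[ctrl_idx] == cvd[i])
      if (config$exclude_same_subject) ok <- ok & (subj[ctrl_idx] != subj[i])
      elig <- ctrl_idx[which(ok)]
      caliper_used <- cal
      if (length(elig) >= config$ratio) break
    }
    n_take <- min(config$ratio, length(elig))
    take <- if (n_take > 0) elig[sample.int(length(elig), n_take)] else integer(0)
    used[take] <- TRUE
    selected <- c(selected, take)
    report[[ci]] <- data.frame(
      case_row = i, subject_id = subj[i], age = age[i],
      caliper_used = caliper_used, n_controls = n_take,
      shortfall = config$ratio - n_take)
  }
  report <- do.call(rbind, report)
  total_short <- sum(report$shortfall)
  if (total_short > 0) {
    msg <- sprintf("%d case(s) matched with fewer than %d controls (total shortfall %d)",
                   sum(report$shortfall > 0), config$ratio, total_short)
    if (config$strict) stop(msg) else warning(msg, call. = FALSE)
  }
  out <- cohort[sort(c(case_idx, selected)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "match_report") <- report
  out
}
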