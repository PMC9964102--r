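#' Monte-Carlo operating characteristics of the framework
#'
#' Runs the full generate -> match -> fit -> step-2 -> step-3 chain on
#' `n_reps` independent replicates of a synthetic scenario and summarises,
#' per factor, the empirical rate of: a magnitude difference detected at the
#' 5% tier, detected at the 10%-or-better tier, a significance-pattern
#' change, proceeding to step 3, and a non-proportional verdict (among reps
#' that reached step 3). Each rate carries an exact (Clopper-Pearson)
#' binomial confidence interval, because simulated rates are estimates with
#' Monte-Carlo error, not fixed values.
#'
#' Replicate seeds are drawn once from `seed`, so every replicate is
#' independently reproducible. Replicate-level failures (e.g., a group with
#' no cases in a tiny scenario) are counted and excluded, not fatal.
#'
#' @param config a [scenario_config()]; its `seed` is overridden per
#'   replicate.
#' @param n_reps number of replicates (>= 1).
#' @param groups an [age_groups()] object.
#' @param match build the 1:2 matched design before fitting (default
#'   `TRUE`).
#' @param match_cfg a [match_config()].
#' @param levels,pattern_level,prop_level significance levels for steps 2-3.
#' @param scaling predictor scaling mode for [fit_stratified()].
#' @param conf_level confidence level of the Monte-Carlo intervals.
#' @param seed master seed for the replicate-seed sequence.
#' @return An object of class `oc_summary`: a per-factor/metric rate table
#'   with confidence bounds, plus `n_reps`, `n_failed`.
#' @export
run_operating_characteristics <- function(config, n_reps,
                                          groups = age_groups(),
                                          match = TRUE,
                                          match_cfg = match_config(),
                                          levels = c(0.05, 0.10),
                                          pattern_level = 0.05,
                                          prop_level = 0.05,
                                          scaling = "pooled",
                                          conf_level = 0.95,
                                          seed = 1L) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  factor_names <- names(config$profiles)
  specs <- default_risk_factors()[factor_names]
  rec <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    res <- tryCatch({
      cohort <- generate_cohort(cfg)
      design <- if (match) {
        mc <- match_cfg
        mc$seed <- NULL  # RNG already seeded via the replicate stream
        suppressWarnings(select_matched_controls(cohort, mc, groups))
      } else cohort
      fits <- fit_stratified(design, specs, groups, scaling = scaling)
      lapply(factor_names, function(f) {
        ff <- fits[fits$factor == f, , drop = FALSE]
        cmp <- magnitude_difference_test(ff, levels)
        pat <- significance_pattern(ff, pattern_level)
        ver <- step2_verdict(cmp, pat)
        nonprop <- NA
        if (ver$proceed_to_step3 && sum(ff$converged) >= 3L) {
          pts <- proportionality_points(ff, groups, cohort = design)
          a <- linearity_assessment(pts, level = prop_level, factor = f)
          nonprop <- a$verdict == "non_proportional"
        }
        data.frame(factor = f,
                   detect_5 = cmp$tier == "significant_5",
                   detect_10 = cmp$tier != "not_significant",
                   significance_changed = pat$changed,
                   proceed = ver$proceed_to_step3,
                   non_proportional = nonprop,
                   stringsAsFactors = FALSE)
      })
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else
      rec[[length(rec) + 1L]] <- do.call(rbind, res)
  }
  if (!length(rec)) stop("all replicates failed")
  all <- do.call(rbind, rec)
  metrics <- c("detect_5", "detect_10", "significance_changed", "proceed",
               "non_proportional")
  rows <- list()
  for (f in unique(all$factor)) {
    sub <- all[all$factor == f, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      ci <- stats::binom.test(sum(v), length(v),
                              conf.level = conf_level)$conf.int
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, metric = m, k = sum(v), n = length(v),
        rate = mean(v), conf_low = ci[1], conf_high = ci[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(rates = out, n_reps = n_reps, n_failed = n_failed,
                 conf_level = conf_level, seed = seed),
            class = "oc_summary")
}

#' @export
print.oc_summary <- function(x, ...) {
  cat(sprintf("<operating characteristics> %d replicates (%d failed), %g%% MC intervals\n",
              x$n_reps, x$n_failed, 100 * x$conf_level))
  print.data.frame(x$rates, digits = 3)
  invisible(x)
}
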