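#' z-test statistic for the difference of two regression coefficients
#'
#' `Z = (b1 - b2) / sqrt(SE1^2 + SE2^2)`, comparing the same risk factor's
#' coefficients from two independently fitted age-group models. The
#' statistic is antisymmetric in the pair ordering.
#'
#' @param b1,b2 the two coefficients.
#' @param se1,se2 their standard errors, strictly positive.
#' @return The z statistic.
#' @export
#' @examples
#' z_statistic(0.70, 0.153, 0.17, 0.037)  # ~3.37
z_statistic <- function(b1, se1, b2, se2) {
  if (any(c(se1, se2) <= 0) || anyNA(c(se1, se2)))
    stop("standard errors must be positive")
  (b1 - b2) / sqrt(se1^2 + se2^2)
}

#' Enumerate all unordered age-group pairs for one factor
#'
#' Lists the `k(k-1)/2` candidate pairs with their absolute coefficient
#' difference and the sum of their standard errors — the two quantities the
#' pair-selection rules rank on. Only converged fits are usable.
#'
#' @param fits `data.frame` of fits for a single factor, in age order, with
#'   columns `group`, `coefficient`, `std_error`, and optionally `converged`.
#' @return A `data.frame` with one row per pair: indices `i`, `j` (age
#'   order), labels `group1`, `group2`, `abs_diff`, `se_sum`.
#' @export
enumerate_group_pairs <- function(fits) {
  conv <- if ("converged" %in% names(fits)) fits$converged else
    rep(TRUE, nrow(fits))
  usable <- which(conv & !is.na(fits$coefficient) & !is.na(fits$std_error))
  if (length(usable) < 2L) stop("fewer than 2 usable fits")
  pairs <- utils::combn(usable, 2L)
  data.frame(
    i = pairs[1L, ], j = pairs[2L, ],
    group1 = fits$group[pairs[1L, ]], group2 = fits$group[pairs[2L, ]],
    abs_diff = abs(fits$coefficient[pairs[1L, ]] - fits$coefficient[pairs[2L, ]]),
    se_sum = fits$std_error[pairs[1L, ]] + fits$std_error[pairs[2L, ]],
    stringsAsFactors = FALSE)
}

# rank pairs: largest |difference| first; exact ties (common with
# two-decimal coefficients) resolve to the pair anchored at the youngest
# group, then the widest age separation, then the smaller SE sum
order_pairs <- function(pairs) {
  pairs[order(-pairs$abs_diff, pairs$i, -pairs$j, pairs$se_sum), ,
        drop = FALSE]
}

#' Select the primary pair to test
#'
#' One difference suffices to show non-constancy, so the pair tested first
#' is the one whose coefficients have the largest difference in magnitude
#' (e.g., with coefficients 0.5, 0.51, 0.7 the pair 0.5 vs 0.7). Exact ties
#' in the difference — frequent when coefficients are reported to two
#' decimals — resolve to the pair anchored at the youngest group, then the
#' widest age separation, then the smaller standard-error sum.
#'
#' @param fits per-factor fits as in [enumerate_group_pairs()].
#' @return A one-row `data.frame` describing the selected pair.
#' @export
select_primary_pair <- function(fits) {
  order_pairs(enumerate_group_pairs(fits))[1L, , drop = FALSE]
}

#' Select the standard-error-gated secondary pair
#'
#' When the primary test is not significant, a second (and last) test is
#' performed only if it can be better powered: among the remaining pairs
#' whose standard-error sum is strictly smaller than the primary pair's, the
#' one with the largest coefficient difference is tested. If no pair has a
#' smaller standard-error sum, no more testing is done and the coefficient
#' magnitudes are declared not different.
#'
#' @param fits per-factor fits.
#' @param primary the pair returned by [select_primary_pair()].
#' @return A one-row `data.frame`, or `NULL` when no eligible pair exists.
#' @export
select_secondary_pair <- function(fits, primary) {
  pairs <- enumerate_group_pairs(fits)
  pairs <- pairs[!(pairs$i == primary$i & pairs$j == primary$j), , drop = FALSE]
  pairs <- pairs[pairs$se_sum < primary$se_sum, , drop = FALSE]
  if (nrow(pairs) == 0L) return(NULL)
  order_pairs(pairs)[1L, , drop = FALSE]
}

tier_of <- function(z, crit5, crit10) {
  if (abs(z) >= crit5) "significant_5"
  else if (abs(z) >= crit10) "significant_10"
  else "not_significant"
}

best_tier <- function(tiers) {
  lv <- c("significant_5", "significant_10", "not_significant")
  lv[min(match(tiers, lv))]
}

tier_label <- function(tier) {
  switch(tier, significant_5 = "Yes (5%)", significant_10 = "Yes (10%)", "No")
}

#' Test for a difference in coefficient magnitudes across age groups
#'
#' The magnitude half of the framework's step 2: test the primary pair with
#' the coefficient-difference z-test; if it is not significant even at the
#' weaker level, test the standard-error-gated secondary pair (at most two
#' tests per factor, to limit multiple testing). The factor's tier is the
#' best tier achieved over the tested pairs, with two-sided normal critical
#' values (1.959964 at 5%, 1.644854 at 10% by default).
#'
#' @param fits per-factor fits (rows in age order).
#' @param levels the two significance levels, strong first (default
#'   `c(0.05, 0.10)`).
#' @return An object of class `coef_comparison`: the tested pair(s) with
#'   their z statistics and per-pair tiers, the factor-level `tier`, and a
#'   `rule_trace` documenting each selection decision.
#' @export
magnitude_difference_test <- function(fits, levels = c(0.05, 0.10)) {
  stopifnot(length(levels) == 2L, all(levels > 0), all(levels < 1),
            levels[1] < levels[2])
  crit <- stats::qnorm(1 - levels / 2)
  trace <- character(0)
  test_pair <- function(p) {
    z <- z_statistic(fits$coefficient[p$i], fits$std_error[p$i],
                     fits$coefficient[p$j], fits$std_error[p$j])
    data.frame(group1 = p$group1, group2 = p$group2,
               b1 = fits$coefficient[p$i], b2 = fits$coefficient[p$j],
               se1 = fits$std_error[p$i], se2 = fits$std_error[p$j],
               Z = z, tier = tier_of(z, crit[1], crit[2]),
               stringsAsFactors = FALSE)
  }
  primary <- select_primary_pair(fits)
  t1 <- test_pair(primary)
  trace <- c(trace, sprintf(
    "primary pair: largest |difference| %.4g is %s vs %s; Z = %.4g (%s)",
    primary$abs_diff, t1$group1, t1$group2, t1$Z, tier_label(t1$tier)))
  tested <- t1
  if (t1$tier == "not_significant") {
    secondary <- select_secondary_pair(fits, primary)
    if (is.null(secondary)) {
      trace <- c(trace, paste(
        "no remaining pair has a strictly smaller standard-error sum than",
        sprintf("the primary pair (%.4g); testing stops", primary$se_sum)))
    } else {
      trace <- c(trace, sprintf(
        paste("secondary pair: largest |difference| among pairs with SE sum <",
              "%.4g (note: ranked by |difference| within the smaller-SE set,",
              "not by second-largest |difference| overall) is %s vs %s",
              "(SE sum %.4g)"),
        primary$se_sum, secondary$group1, secondary$group2, secondary$se_sum))
      t2 <- test_pair(secondary)
      trace <- c(trace, sprintf("secondary Z = %.4g (%s)", t2$Z,
                                tier_label(t2$tier)))
      tested <- rbind(t1, t2)
    }
  }
  structure(list(factor = fits$factor[1L], tested_pairs = tested,
                 tier = best_tier(tested$tier), levels = levels,
                 critical_values = crit, rule_trace = trace),
            class = "coef_comparison")
}

#' @export
print.coef_comparison <- function(x, ...) {
  cat(sprintf("<coefficient comparison> %s: %s\n", x$factor,
              tier_label(x$tier)))
  tp <- x$tested_pairs
  for (r in seq_len(nrow(tp))) {
    cat(sprintf("  %s (%.2f) vs %s (%.2f): Z = %.3f  %s\n",
                tp$group1[r], tp$b1[r], tp$group2[r], tp$b2[r], tp$Z[r],
                tier_label(tp$tier[r])))
  }
  invisible(x)
}

#' Per-group significance pattern of a factor's coefficients
#'
#' The fallback half of step 2: when coefficient magnitudes do not differ
#' decisively, a change in which age groups have statistically significant
#' coefficients still indicates a change in the factor's importance with
#' age. Flags each group's Wald p-value against `level` (and, for
#' reference, against `secondary_level`); `changed` is `TRUE` when not all
#' groups share the same status at `level`.
#'
#' @param fits per-factor fits with `p_value` available for all groups.
#' @param level primary significance level (default 0.05).
#' @param secondary_level also-reported weaker level (default 0.10).
#' @return An object of class `significance_pattern`.
#' @export
significance_pattern <- function(fits, level = 0.05, secondary_level = 0.10) {
  if (anyNA(fits$p_value)) stop("p-values must be available for all groups")
  flags <- stats::setNames(fits$p_value < level, fits$group)
  flags2 <- stats::setNames(fits$p_value < secondary_level, fits$group)
  structure(list(factor = fits$factor[1L], level = level,
                 secondary_level = secondary_level,
                 flags = flags, flags_secondary = flags2,
                 changed = length(unique(flags)) > 1L),
            class = "significance_pattern")
}

#' @export
print.significance_pattern <- function(x, ...) {
  cat(sprintf("<significance pattern> %s at %g%%: %s (changed: %s)\n",
              x$factor, 100 * x$level,
              paste(names(x$flags), ifelse(x$flags, "sig", "ns"),
                    sep = "=", collapse = ", "),
              x$changed))
  invisible(x)
}

#' Step-2 verdict: does the factor proceed to the proportionality check?
#'
#' A factor moves to step 3 when its coefficient magnitudes differ (any
#' significance tier) or when the significance pattern changes across age
#' groups. Mirroring the framework's decision flow, the pattern is only
#' consulted when the magnitude test did not already settle the question at
#' the strong level.
#'
#' @param comparison a [magnitude_difference_test()] result.
#' @param pattern a [significance_pattern()] for the same factor.
#' @return An object of class `step2_verdict` with fields
#'   `magnitude_tier`, `significance_changed`, `pattern_consulted`, and
#'   `proceed_to_step3`.
#' @export
step2_verdict <- function(comparison, pattern) {
  if (!identical(comparison$factor, pattern$factor))
    stop("comparison and pattern refer to different factors")
  consulted <- comparison$tier != "significant_5"
  structure(list(factor = comparison$factor,
                 magnitude_tier = comparison$tier,
                 significance_changed = pattern$changed,
                 pattern_consulted = consulted,
                 proceed_to_step3 = comparison$tier != "not_significant" ||
                   pattern$changed),
            class = "step2_verdict")
}

#' @export
print.step2_verdict <- function(x, ...) {
  cat(sprintf("<step-2 verdict> %s: tier %s, significance changed %s -> %s\n",
              x$factor, x$magnitude_tier, x$significance_changed,
              if (x$proceed_to_step3) "check proportionality (step 3)"
              else "stop (no change with age)"))
  invisible(x)
}

#' Run step 2 for every factor in a stratified fit table
#'
#' Applies [magnitude_difference_test()], [significance_pattern()] and
#' [step2_verdict()] per factor and assembles a tidy summary with one row
#' per tested pair (the conventional comparison-table layout).
#'
#' Factors with fewer than two converged group fits cannot be compared;
#' they are listed in `skipped` rather than raising an error, so one sparse
#' stratum does not abort a whole run. Non-converged fits are likewise
#' excluded from the significance pattern.
#'
#' @param fits a `stratified_fits` data frame (all factors).
#' @param levels magnitude-test significance levels (default
#'   `c(0.05, 0.10)`).
#' @param pattern_level level for the significance-pattern flags (default
#'   0.05).
#' @return A list of class `step2_results`: named lists `comparisons`,
#'   `patterns`, `verdicts`, a `summary` data frame, and `skipped` factor
#'   names.
#' @export
compare_factors <- function(fits, levels = c(0.05, 0.10),
                            pattern_level = 0.05) {
  factors <- unique(fits$factor)
  comparisons <- patterns <- verdicts <- stats::setNames(
    vector("list", length(factors)), factors)
  rows <- list()
  skipped <- character(0)
  for (f in factors) {
    ff <- fits[fits$factor == f, , drop = FALSE]
    ff <- ff[ff$converged & !is.na(ff$p_value), , drop = FALSE]
    if (nrow(ff) < 2L) {
      skipped <- c(skipped, f)
      comparisons[[f]] <- patterns[[f]] <- verdicts[[f]] <- NULL
      next
    }
    cmp <- magnitude_difference_test(ff, levels)
    pat <- significance_pattern(ff, pattern_level)
    ver <- step2_verdict(cmp, pat)
    comparisons[[f]] <- cmp; patterns[[f]] <- pat; verdicts[[f]] <- ver
    tp <- cmp$tested_pairs
    rows[[f]] <- data.frame(factor = f, tp,
                            significant = vapply(tp$tier, tier_label, ""),
                            proceed_to_step3 = ver$proceed_to_step3,
                            stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(comparisons = comparisons, patterns = patterns,
                 verdicts = verdicts, summary = summary, skipped = skipped),
            class = "step2_results")
}

#' @export
print.step2_results <- function(x, ...) {
  cat("<step-2 results>\n")
  print.data.frame(x$summary[, c("factor", "group1", "b1", "group2", "b2",
                                 "Z", "significant", "proceed_to_step3")],
                   digits = 3)
  invisible(x)
}
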