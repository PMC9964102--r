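#' Age/coefficient points for the proportionality assessment
#'
#' For each age group with a converged fit, pairs the group's coefficient
#' (and standard error) with an age coordinate: the integer-age midpoint for
#' bounded groups (54.5 for "50 to 59") and the median observed age — or an
#' explicit override — for the open-ended youngest/oldest groups (see
#' [age_group_midpoint()]).
#'
#' @param fits per-factor fits (one row per age group).
#' @param groups an [age_groups()] object.
#' @param cohort optional cohort supplying observed ages for open-ended
#'   groups.
#' @param age_coordinates optional named numeric vector
#'   (`c("under 50" = 44, ...)`) overriding the coordinate of any group.
#' @return A `data.frame` with columns `group`, `age`, `coefficient`,
#'   `std_error`.
#' @export
proportionality_points <- function(fits, groups = age_groups(), cohort = NULL,
                                   age_coordinates = NULL) {
  keep <- fits$converged & !is.na(fits$coefficient) & !is.na(fits$std_error)
  ff <- fits[keep, , drop = FALSE]
  grp_assign <- if (!is.null(cohort)) assign_age_group(cohort$age, groups)
  age <- vapply(ff$group, function(g) {
    ages <- if (!is.null(cohort)) cohort$age[grp_assign == g] else NULL
    override <- if (!is.null(age_coordinates) && g %in% names(age_coordinates))
      age_coordinates[[g]] else NULL
    age_group_midpoint(groups, g, ages = ages, override = override)
  }, numeric(1))
  data.frame(group = ff$group, age = unname(age),
             coefficient = ff$coefficient, std_error = ff$std_error,
             stringsAsFactors = FALSE)
}

#' Assess proportionality as linearity of coefficient versus age
#'
#' If a factor's contribution is proportional to age, the coefficients
#' plotted against the age-group coordinates fall on a straight line. This
#' function fits that line by weighted least squares (weights `1/SE^2` by
#' default) and computes a lack-of-fit chi-square,
#' `sum(((b_i - fitted_i)/SE_i)^2)`, referred to a chi-square distribution
#' with `(number of points - 2)` degrees of freedom. The verdict is
#' `"non_proportional"` when the lack-of-fit p-value is below `level`,
#' `"proportional"` otherwise — and `"indeterminate"` with only two points,
#' since a line always fits two points exactly. The unweighted (OLS line)
#' variant of the statistic is reported alongside for sensitivity.
#'
#' @param points `data.frame` from [proportionality_points()] (columns
#'   `age`, `coefficient`, `std_error`; positive standard errors).
#' @param level significance level for the lack-of-fit test (default 0.05).
#' @param weighted fit the line by `1/SE^2`-weighted least squares
#'   (default) or ordinary least squares.
#' @param factor optional factor name carried into the result.
#' @return An object of class `proportionality`: the points, fitted `slope`
#'   (coefficient units per year) and `intercept`, `statistic`, `df`,
#'   `p_value`, `verdict`, and an `alternative` list with the other
#'   weighting's numbers.
#' @export
linearity_assessment <- function(points, level = 0.05, weighted = TRUE,
                                 factor = NA_character_) {
  stopifnot(is.data.frame(points),
            all(c("age", "coefficient", "std_error") %in% names(points)))
  n <- nrow(points)
  if (n < 2L) stop("at least 2 points are required")
  if (any(points$std_error <= 0 | is.na(points$std_error)))
    stop("standard errors must be positive")
  w <- 1 / points$std_error^2
  line_fit <- function(use_weights) {
    if (use_weights)
      stats::lm(coefficient ~ age, data = points, weights = w)
    else stats::lm(coefficient ~ age, data = points)
  }
  lof <- function(fit) sum(w * stats::residuals(fit)^2)
  if (n == 2L) {
    slope <- diff(points$coefficient) / diff(points$age)
    intercept <- points$coefficient[1L] - slope * points$age[1L]
    res <- list(factor = factor, points = points, slope = slope,
                intercept = intercept, statistic = 0, df = 0L,
                p_value = NA_real_, verdict = "indeterminate",
                level = level, weighted = weighted, alternative = NULL)
    return(structure(res, class = "proportionality"))
  }
  fit_main <- line_fit(weighted)
  fit_alt <- line_fit(!weighted)
  stat <- lof(fit_main)
  df <- n - 2L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  stat_alt <- lof(fit_alt)
  structure(list(
    factor = factor, points = points,
    slope = unname(stats::coef(fit_main)[2L]),
    intercept = unname(stats::coef(fit_main)[1L]),
    statistic = stat, df = df, p_value = p,
    verdict = if (p < level) "non_proportional" else "proportional",
    level = level, weighted = weighted,
    alternative = list(weighted = !weighted, statistic = stat_alt,
                       p_value = stats::pchisq(stat_alt, df, lower.tail = FALSE),
                       slope = unname(stats::coef(fit_alt)[2L]),
                       intercept = unname(stats::coef(fit_alt)[1L]))),
    class = "proportionality")
}

#' @export
print.proportionality <- function(x, ...) {
  cat(sprintf(
    "<proportionality> %s: %s (lack-of-fit X2 = %.3g on %d df, p = %.3g)\n",
    x$factor %||% "?", x$verdict, x$statistic, x$df,
    if (is.na(x$p_value)) NA else x$p_value))
  invisible(x)
}

#' Run step 3 for a set of factors
#'
#' @param fits a `stratified_fits` data frame.
#' @param groups an [age_groups()] object.
#' @param cohort,age_coordinates passed to [proportionality_points()].
#' @param level lack-of-fit level.
#' @param weighted weighting of the line fit.
#' @param factors factor names to assess (default: all in `fits`).
#' @return A list of class `step3_results`: named list `assessments` and a
#'   tidy `summary` data frame (factor, slope, intercept, statistic, df, p,
#'   verdict).
#' @export
assess_proportionality <- function(fits, groups = age_groups(), cohort = NULL,
                                   age_coordinates = NULL, level = 0.05,
                                   weighted = TRUE,
                                   factors = unique(fits$factor)) {
  assessments <- stats::setNames(vector("list", length(factors)), factors)
  rows <- list()
  for (f in factors) {
    ff <- fits[fits$factor == f, , drop = FALSE]
    pts <- proportionality_points(ff, groups, cohort, age_coordinates)
    a <- linearity_assessment(pts, level = level, weighted = weighted,
                              factor = f)
    assessments[[f]] <- a
    rows[[f]] <- data.frame(factor = f, n_points = nrow(pts),
                            slope = a$slope, intercept = a$intercept,
                            statistic = a$statistic, df = a$df,
                            p_value = a$p_value, verdict = a$verdict,
                            stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(assessments = assessments, summary = summary),
            class = "step3_results")
}

#' @export
print.step3_results <- function(x, ...) {
  cat("<step-3 results>\n")
  print.data.frame(x$summary, digits = 3)
  invisible(x)
}

#' Plot coefficient versus age with fitted lines
#'
#' One panel per factor: the per-group coefficients at their age
#' coordinates, +/-1 SE bars, the fitted proportionality line, and the
#' verdict in the panel strip. This is the framework's visual check; the
#' lack-of-fit statistic is its quantitative surrogate.
#'
#' @param results a `step3_results` object or a list of `proportionality`
#'   objects.
#' @param path optional output file (extension selects the device, e.g.,
#'   `.png`, `.svg`, `.pdf`); when `NULL` the ggplot object is returned.
#' @param width,height,dpi device settings passed to [ggplot2::ggsave()].
#' @return The ggplot object (invisibly when written to `path`).
#' @export
plot_proportionality <- function(results, path = NULL, width = 9, height = 6,
                                 dpi = 150) {
  assessments <- if (inherits(results, "step3_results")) results$assessments
                 else results
  assessments <- Filter(Negate(is.null), assessments)
  if (!length(assessments)) stop("no proportionality results to plot")
  pts <- do.call(rbind, lapply(assessments, function(a) {
    disp <- factor_display_names()
    nm <- if (!is.na(a$factor) && a$factor %in% names(disp)) disp[[a$factor]]
          else a$factor
    cbind(a$points,
          panel = sprintf("%s [%s]", nm, a$verdict),
          slope = a$slope, intercept = a$intercept)
  }))
  g <- ggplot2::ggplot(pts, ggplot2::aes(x = age, y = coefficient)) +
    ggplot2::geom_abline(ggplot2::aes(slope = slope, intercept = intercept),
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = coefficient - std_error,
                                        ymax = coefficient + std_error),
                           width = 1.2, colour = "grey55") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = "Model coefficient (log-odds)") +
    ggplot2::theme_bw(base_size = 10)
  if (!is.null(path)) {
    ggplot2::ggsave(path, g, width = width, height = height, dpi = dpi)
    return(invisible(g))
  }
  g
}
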