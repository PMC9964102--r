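#' Standardize a predictor
#'
#' Returns `(values - center) / scale`. Used to put continuous risk factors
#' on a common scale before fitting, so that coefficients from different age
#' groups are in identical units and can be compared directly.
#'
#' @param values numeric vector.
#' @param center centering constant.
#' @param scale scaling constant, strictly positive.
#' @return The standardized vector.
#' @export
standardize_factor <- function(values, center = 0, scale = 1) {
  stopifnot(is.numeric(values), is.numeric(center), is.numeric(scale),
            length(center) == 1L, length(scale) == 1L)
  if (scale <= 0) stop("scale must be > 0")
  (values - center) / scale
}

#' Fit one single-variable logistic regression
#'
#' Maximum-likelihood fit of `stroke_within_window ~ factor` (intercept plus
#' one predictor) by iteratively reweighted least squares, with a
#' convergence tolerance of 1e-10 on the relative deviance change and at
#' most 100 iterations. The standard error is the Wald standard error from
#' the inverse information at the optimum (observed and expected coincide
#' for the logistic canonical link), and the p-value is the two-sided normal
#' tail probability of `coefficient / std_error`.
#'
#' @param data sub-cohort `data.frame` with at least one case and one
#'   control.
#' @param factor a [risk_factor_spec()] or a factor name.
#' @param center,scale standardization applied to the predictor before
#'   fitting when the factor is continuous (categorical factors pass
#'   through unchanged).
#' @param group optional group label recorded in the result.
#' @return A one-row `data.frame` with columns `factor`, `group`,
#'   `coefficient`, `std_error`, `p_value`, `n`, `n_events`, `converged`,
#'   `center`, `scale`. Under complete separation the fit is flagged
#'   `converged = FALSE` and `std_error`/`p_value` are `NA`.
#' @export
fit_single_factor_logistic <- function(data, factor, center = 0, scale = 1,
                                       group = NA_character_) {
  spec <- if (inherits(factor, "risk_factor_spec")) factor else
    risk_factor_spec(factor, "continuous")
  if (!spec$name %in% names(data))
    abort_schema(sprintf("missing required column: %s", spec$name))
  y <- data$stroke_within_window
  x <- data[[spec$name]]
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (sum(y == 1) < 1L || sum(y == 0) < 1L)
    stop("subcohort needs at least one case and one control")
  if (length(unique(x)) < 2L)
    stop(sprintf("degenerate predictor: %s is constant", spec$name))
  if (spec$kind == "continuous") {
    x <- standardize_factor(x, center, scale)
  } else {
    center <- 0; scale <- 1
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit)[2L])
  se <- sqrt(diag(stats::vcov(fit)))[2L]
  converged <- isTRUE(fit$converged) && !separation && is.finite(se) && se < 1e3
  if (!converged) {
    se <- NA_real_; p <- NA_real_
  } else {
    p <- 2 * stats::pnorm(-abs(b / se))
  }
  data.frame(factor = spec$name, group = group, coefficient = b,
             std_error = unname(se), p_value = unname(p),
             n = length(y), n_events = sum(y == 1),
             converged = converged, center = center, scale = scale,
             stringsAsFactors = FALSE)
}

#' Fit single-factor logistic models per risk factor and age group
#'
#' The framework's step 1: split the design set by age group and fit, for
#' every (risk factor, age group) combination, a separate single-variable
#' logistic regression. Continuous factors are z-scored; with the default
#' `scaling = "pooled"` the mean/SD are computed on the whole design set, so
#' coefficients from different age groups share units — a prerequisite for
#' the cross-group coefficient comparison of step 2. `scaling = "group"`
#' standardizes within each age group; `scaling = "none"` leaves predictors
#' on their measurement scale; `scaling = "manual"` uses the supplied
#' `centers`/`scales`.
#'
#' @param cohort design-set cohort `data.frame`.
#' @param factors list of [risk_factor_spec()].
#' @param groups an [age_groups()] object.
#' @param scaling one of `"pooled"`, `"group"`, `"none"`, `"manual"`.
#' @param centers,scales named numeric vectors (by factor name) used when
#'   `scaling = "manual"`.
#' @return A `data.frame` of class `stratified_fits` with one row per
#'   (factor, group); rows where the fit was impossible (empty group, no
#'   cases, constant predictor) carry `NA` estimates and `converged = FALSE`.
#'   The scaling mode and constants are attached as attributes.
#' @export
fit_stratified <- function(cohort, factors = default_risk_factors(),
                           groups = age_groups(),
                           scaling = c("pooled", "group", "none", "manual"),
                           centers = NULL, scales = NULL) {
  scaling <- match.arg(scaling)
  subcohorts <- split_by_age(cohort, groups)
  cont <- Filter(function(f) f$kind == "continuous", factors)
  cont_names <- vapply(cont, `[[`, character(1), "name")
  pooled_center <- vapply(cont_names, function(nm)
    mean(cohort[[nm]], na.rm = TRUE), numeric(1))
  pooled_scale <- vapply(cont_names, function(nm)
    stats::sd(cohort[[nm]], na.rm = TRUE), numeric(1))
  if (scaling == "manual") {
    stopifnot(!is.null(centers), !is.null(scales),
              all(cont_names %in% names(centers)),
              all(cont_names %in% names(scales)))
  }
  rows <- list()
  for (g in names(subcohorts)) {
    sub <- subcohorts[[g]]
    for (f in factors) {
      cs <- c(0, 1)
      if (f$kind == "continuous") {
        cs <- switch(scaling,
          pooled = c(pooled_center[f$name], pooled_scale[f$name]),
          group = c(mean(sub[[f$name]], na.rm = TRUE),
                    stats::sd(sub[[f$name]], na.rm = TRUE)),
          none = c(0, 1),
          manual = c(centers[f$name], scales[f$name]))
      }
      row <- tryCatch(
        fit_single_factor_logistic(sub, f, center = cs[1], scale = cs[2],
                                   group = g),
        error = function(e) data.frame(
          factor = f$name, group = g, coefficient = NA_real_,
          std_error = NA_real_, p_value = NA_real_,
          n = nrow(sub), n_events = sum(sub$stroke_within_window == 1),
          converged = FALSE, center = cs[1], scale = cs[2],
          stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, scaling = scaling, groups = groups,
            class = c("stratified_fits", "data.frame"))
}

#' @export
print.stratified_fits <- function(x, ...) {
  cat(sprintf("<stratified fits> %d factor x group models (scaling: %s)\n",
              nrow(x), attr(x, "scaling") %||% "?"))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Reshape stratified fits into a wide per-factor table
#'
#' One row per risk factor, with coefficient / standard error / p-value
#' columns per age group — the layout conventionally used to report
#' age-stratified single-factor models.
#'
#' @param fits a `stratified_fits` data frame.
#' @return A wide `data.frame`.
#' @export
fits_wide_table <- function(fits) {
  groups <- unique(fits$group)
  factors <- unique(fits$factor)
  out <- data.frame(factor = factors, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- fits[fits$group == g, ]
    m <- match(factors, sub$factor)
    safe <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
    out[[paste0("coef_", safe(g))]] <- sub$coefficient[m]
    out[[paste0("se_", safe(g))]] <- sub$std_error[m]
    out[[paste0("p_", safe(g))]] <- sub$p_value[m]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
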