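#' Age-dependent effect profile
#'
#' Describes how a risk factor's true log-odds effect varies with age in a
#' synthetic scenario. `constant` and `linear` profiles are proportional
#' truths (coefficient vs age is a line); `step` and `quadratic` profiles
#' are non-proportional truths.
#'
#' Modes and parameters:
#' \describe{
#'   \item{constant}{`value`: the effect at every age.}
#'   \item{linear}{`intercept + slope * age`.}
#'   \item{step}{`levels` (length `m`), `breakpoints` (length `m - 1`,
#'     increasing); ages below the first breakpoint get `levels[1]`, ages at
#'     or above breakpoint `j` move to `levels[j + 1]`.}
#'   \item{quadratic}{`a + b * age + c * age^2`.}
#' }
#'
#' @param mode one of `"constant"`, `"linear"`, `"step"`, `"quadratic"`.
#' @param value,intercept,slope,levels,breakpoints,a,b,c mode parameters.
#' @return An object of class `beta_profile`.
#' @export
#' @examples
#' eval_beta_profile(beta_profile("linear", intercept = 0, slope = 0.01), 54.5)
#' eval_beta_profile(beta_profile("step", levels = c(0.5, 0.1),
#'                                breakpoints = 60), c(59, 60))
beta_profile <- function(mode = c("constant", "linear", "step", "quadratic"),
                         value = NULL, intercept = NULL, slope = NULL,
                         levels = NULL, breakpoints = NULL,
                         a = NULL, b = NULL, c = NULL) {
  mode <- match.arg(mode)
  params <- switch(mode,
    constant = {
      stopifnot(is.numeric(value), length(value) == 1L)
      list(value = value)
    },
    linear = {
      stopifnot(is.numeric(intercept), is.numeric(slope))
      list(intercept = intercept, slope = slope)
    },
    step = {
      stopifnot(is.numeric(levels), length(levels) >= 2L,
                is.numeric(breakpoints),
                length(breakpoints) == length(levels) - 1L,
                !is.unsorted(breakpoints, strictly = TRUE))
      list(levels = levels, breakpoints = breakpoints)
    },
    quadratic = {
      stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
      list(a = a, b = b, c = c)
    })
  structure(list(mode = mode, params = params), class = "beta_profile")
}

#' Evaluate an effect profile at given ages
#'
#' @param profile a [beta_profile()].
#' @param age numeric vector of ages in years.
#' @return The log-odds effect at each age.
#' @export
eval_beta_profile <- function(profile, age) {
  stopifnot(inherits(profile, "beta_profile"))
  p <- profile$params
  switch(profile$mode,
    constant = rep(p$value, length(age)),
    linear = p$intercept + p$slope * age,
    step = p$levels[findInterval(age, p$breakpoints) + 1L],
    quadratic = p$a + p$b * age + p$c * age^2,
    stop(sprintf("unknown profile mode: %s", profile$mode)))
}

#' Is a profile a proportional (linear-in-age) truth?
#' @param profile a [beta_profile()].
#' @return `TRUE` for constant and linear profiles.
#' @export
is_proportional_truth <- function(profile) {
  profile$mode %in% c("constant", "linear")
}

#' @export
print.beta_profile <- function(x, ...) {
  cat(sprintf("<beta profile> %s(%s)\n", x$mode,
              paste(names(x$params),
                    vapply(x$params, function(v) paste(signif(v, 4), collapse = ","), ""),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Default age-dependent factor distributions
#'
#' Continuous factors follow normal distributions whose means drift mildly
#' and linearly with age (systolic/diastolic pressure, total cholesterol and
#' BMI all rise with age in observational cohorts); binary condition
#' indicators have logistic-in-age prevalences (atrial fibrillation and
#' treated hypertension become more common with age, sex is age-constant at
#' 0.5). Each continuous entry also fixes the reference `center`/`scale`
#' (its mean at the reference age and its SD) on which true effects act.
#'
#' @param ref_age reference age in years for the effect scale (default 60).
#' @return A named list of per-factor generator models.
#' @export
default_factor_models <- function(ref_age = 60) {
  cont <- function(base, slope, sd) {
    force(base); force(slope); force(sd)
    list(kind = "continuous", mean = function(age) base + slope * age,
         sd = sd, center = base + slope * ref_age, scale = sd)
  }
  bin <- function(intercept, slope) {
    force(intercept); force(slope)
    list(kind = "categorical",
         prevalence = function(age) stats::plogis(intercept + slope * age))
  }
  list(
    systolic_bp = cont(95, 0.55, 15),
    diastolic_bp = cont(68, 0.18, 10),
    total_cholesterol = cont(155, 0.75, 40),
    bmi = cont(22, 0.07, 4),
    sex = bin(0, 0),                      # prevalence 0.5 at all ages
    atrial_fibrillation = bin(-9, 0.09),
    hbp_treatment = bin(-5, 0.06)
  )
}

default_profiles <- function() {
  list(
    systolic_bp = beta_profile("constant", value = 0.5),
    diastolic_bp = beta_profile("constant", value = 0.45),
    total_cholesterol = beta_profile("constant", value = 0.2),
    bmi = beta_profile("constant", value = 0.2),
    sex = beta_profile("constant", value = 0.1),
    atrial_fibrillation = beta_profile("constant", value = 1.5),
    hbp_treatment = beta_profile("constant", value = 0.2)
  )
}

#' Synthetic-cohort scenario configuration
#'
#' Defines the generative truth for a synthetic exam cohort: the age
#' distribution, per-factor distributions, the baseline log-odds of a
#' within-window stroke as a function of age, and each factor's true
#' age-dependent effect profile. Continuous-factor effects act on the
#' standardized value `(x - center)/scale` using the fixed reference
#' center/scale recorded in `factor_models`, so the truth is in the same
#' units as a standardized model coefficient.
#'
#' @param n_subjects number of subjects.
#' @param exams_per_subject integer range `c(min, max)` of exams per subject
#'   (drawn uniformly); a scalar fixes the count.
#' @param exam_spacing years between consecutive exams (default 2); factor
#'   values are re-drawn at each exam around the aged-forward mean.
#' @param age_range `c(min, max)` for the age at first exam, in years.
#' @param age_shape `"uniform"` or `"peaked"` (a symmetric beta(2,2) bump).
#' @param baseline `c(intercept, slope)`: baseline log-odds
#'   `intercept + slope * (age - ref_age)`.
#' @param ref_age reference age for the baseline and effect scales.
#' @param profiles named list of [beta_profile()] objects (any subset of the
#'   factor names; omitted factors get effect 0).
#' @param factor_models per-factor generator models, see
#'   [default_factor_models()].
#' @param cvd_model `c(intercept, slope)` for the logistic-in-age prevalence
#'   of cardiovascular disease (used for matching).
#' @param window_years prediction window (default 5).
#' @param missing_rate probability that any one factor cell is blanked, to
#'   exercise the missing-data rules (default 0).
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_subjects = 4000, exams_per_subject = c(1, 3),
                            exam_spacing = 2, age_range = c(30, 90),
                            age_shape = c("uniform", "peaked"),
                            baseline = c(intercept = -4.5, slope = 0.05),
                            ref_age = 60,
                            profiles = default_profiles(),
                            factor_models = default_factor_models(ref_age),
                            cvd_model = c(intercept = -6.5, slope = 0.07),
                            window_years = 5, missing_rate = 0, seed = 1L) {
  age_shape <- match.arg(age_shape)
  stopifnot(n_subjects >= 1, length(age_range) == 2L,
            age_range[1] >= 0, age_range[2] > age_range[1],
            window_years > 0, missing_rate >= 0, missing_rate <= 1,
            exam_spacing > 0)
  if (length(exams_per_subject) == 1L)
    exams_per_subject <- rep(exams_per_subject, 2L)
  stopifnot(exams_per_subject[1] >= 1,
            exams_per_subject[2] >= exams_per_subject[1])
  stopifnot(all(names(profiles) %in% names(factor_models)))
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    stopifnot(inherits(pr, "beta_profile"))
    if (pr$mode == "step" &&
        (any(pr$params$breakpoints <= age_range[1]) ||
         any(pr$params$breakpoints >= age_range[2])))
      stop(sprintf("step breakpoints for '%s' must lie inside the age range", nm))
  }
  for (fm in factor_models) {
    if (fm$kind == "continuous" && fm$sd <= 0) stop("factor SDs must be > 0")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 exams_per_subject = as.integer(exams_per_subject),
                 exam_spacing = exam_spacing, age_range = age_range,
                 age_shape = age_shape, baseline = baseline,
                 ref_age = ref_age, profiles = profiles,
                 factor_models = factor_models, cvd_model = cvd_model,
                 window_years = window_years, missing_rate = missing_rate,
                 seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario> %d subjects, %d-%d exams each, ages %g-%g (%s), window %g y, seed %s\n",
    x$n_subjects, x$exams_per_subject[1], x$exams_per_subject[2],
    x$age_range[1], x$age_range[2], x$age_shape, x$window_years,
    format(x$seed)))
  for (nm in names(x$profiles))
    cat(sprintf("  %s: %s(%s)\n", nm, x$profiles[[nm]]$mode,
                paste(signif(unlist(x$profiles[[nm]]$params), 3), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic exam cohort
#'
#' Draws subjects with ages from the configured distribution, 1 or more
#' exams per subject spaced `exam_spacing` years apart (factor values
#' re-drawn around the aged-forward mean at each exam, emulating repeated
#' clinical exams), and a within-window stroke outcome per exam from
#' `Bernoulli(plogis(alpha(age) + sum_f beta_f(age) * x_f))`, where
#' continuous `x_f` are on the fixed reference-standardized scale. A
#' subject's exams at or after their first stroke are not emitted, and
#' `first_stroke_time` is set within the window after the flagged exam, so
#' the output is consistent under [flag_outcomes()]. Output columns follow
#' the [read_cohort()] schema exactly.
#'
#' The generative truth (profiles, baseline, reference scalings) is
#' attached as the `"truth"` attribute.
#'
#' @param config a [scenario_config()].
#' @return A cohort `data.frame`, reproducible byte-for-byte from
#'   `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  rng <- config$age_range
  age0 <- switch(config$age_shape,
    uniform = stats::runif(n, rng[1], rng[2]),
    peaked = rng[1] + diff(rng) * stats::rbeta(n, 2, 2))
  k <- if (config$exams_per_subject[1] == config$exams_per_subject[2])
    rep(config$exams_per_subject[1], n)
  else
    sample(seq(config$exams_per_subject[1], config$exams_per_subject[2]),
           n, replace = TRUE)
  fm <- config$factor_models
  sex_subj <- stats::rbinom(n, 1,
    if (!is.null(fm$sex)) fm$sex$prevalence(age0) else 0.5)
  idx <- rep(seq_len(n), k)
  exam_no <- sequence(k)
  exam_time <- (exam_no - 1) * config$exam_spacing
  age <- age0[idx] + exam_time
  N <- length(idx)

  x <- list()
  eta_effects <- 0
  for (nm in names(fm)) {
    m <- fm[[nm]]
    if (nm == "sex") {
      x[[nm]] <- sex_subj[idx]
    } else if (m$kind == "continuous") {
      x[[nm]] <- m$mean(age) + stats::rnorm(N, 0, m$sd)
    } else {
      x[[nm]] <- stats::rbinom(N, 1, m$prevalence(age))
    }
    if (nm %in% names(config$profiles)) {
      beta <- eval_beta_profile(config$profiles[[nm]], age)
      xf <- if (m$kind == "continuous")
        (x[[nm]] - m$center) / m$scale else x[[nm]]
      eta_effects <- eta_effects + beta * xf
    }
  }
  cvd <- stats::rbinom(N, 1, stats::plogis(
    config$cvd_model[["intercept"]] + config$cvd_model[["slope"]] * age))
  alpha <- config$baseline[["intercept"]] +
    config$baseline[["slope"]] * (age - config$ref_age)
  y <- stats::rbinom(N, 1, stats::plogis(alpha + eta_effects))

  # drop exams after a subject's first within-window stroke
  prior_strokes <- stats::ave(y, idx, FUN = function(v) cumsum(c(0, v[-length(v)])))
  keep <- prior_strokes == 0
  first_stroke <- rep(NA_real_, N)
  flagged <- keep & y == 1
  first_stroke[flagged] <- exam_time[flagged] +
    stats::runif(sum(flagged), 0, config$window_years)

  out <- data.frame(
    subject_id = sprintf("S%06d", idx),
    exam_time = exam_time,
    age = age,
    systolic_bp = x$systolic_bp,
    diastolic_bp = x$diastolic_bp,
    total_cholesterol = x$total_cholesterol,
    bmi = x$bmi,
    sex = x$sex,
    atrial_fibrillation = x$atrial_fibrillation,
    hbp_treatment = x$hbp_treatment,
    cvd_status = cvd,
    stroke_within_window = y,
    first_stroke_time = first_stroke,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL

  if (config$missing_rate > 0) {
    for (nm in names(fm)) {
      blank <- stats::runif(nrow(out)) < config$missing_rate
      out[[nm]][blank] <- NA
    }
  }
  ref <- do.call(rbind, lapply(names(fm), function(nm) {
    m <- fm[[nm]]
    data.frame(factor = nm,
               center = if (m$kind == "continuous") m$center else 0,
               scale = if (m$kind == "continuous") m$scale else 1,
               stringsAsFactors = FALSE)
  }))
  attr(out, "truth") <- list(profiles = config$profiles,
                             baseline = config$baseline,
                             ref_age = config$ref_age,
                             reference_scaling = ref,
                             window_years = config$window_years,
                             seed = config$seed)
  out
}

#' Single-factor scenario for estimator checks
#'
#' One continuous factor (systolic blood pressure) with a constant true
#' effect, an age-flat factor distribution and an age-flat baseline, so the
#' marginal single-factor fit is unconfounded by age and the constant
#' `beta` is the exact estimand at any scale.
#'
#' @param beta true constant effect per SD of the factor.
#' @param n_subjects subjects (one exam each).
#' @param baseline_logit baseline log-odds (default `qlogis(0.05)`).
#' @param seed RNG seed.
#' @return A [scenario_config()].
#' @export
scenario_single_factor <- function(beta = 0.5, n_subjects = 20000,
                                   baseline_logit = stats::qlogis(0.05),
                                   seed = 1L) {
  fm <- default_factor_models()
  fm$systolic_bp$mean <- function(age) 125
  fm$systolic_bp$center <- 125
  scenario_config(
    n_subjects = n_subjects, exams_per_subject = 1,
    baseline = c(intercept = baseline_logit, slope = 0),
    profiles = list(systolic_bp = beta_profile("constant", value = beta)),
    factor_models = fm, seed = seed)
}

#' Null scenario: identical true coefficients in every age group
#'
#' The factor's effect is constant in age and its distribution and the
#' baseline risk are age-flat, so the age-group models estimate one common
#' coefficient; any detected magnitude difference is a false positive.
#'
#' @param beta common true effect.
#' @param n_subjects subjects (one exam each).
#' @param seed RNG seed.
#' @return A [scenario_config()].
#' @export
scenario_null <- function(beta = 0.3, n_subjects = 3000, seed = 1L) {
  cfg <- scenario_single_factor(beta = beta, n_subjects = n_subjects,
                                seed = seed)
  cfg$baseline <- c(intercept = stats::qlogis(0.06), slope = 0)
  cfg
}

#' Step scenario: a non-proportional truth with a large level gap
#'
#' The factor's effect drops from `level_young` to `level_old` at
#' `breakpoint`; coefficient-versus-age is a step, not a line, so the
#' proportionality verdict should be non-proportional once standard errors
#' are small.
#'
#' @param level_young,level_old effects below/at-or-above the breakpoint.
#' @param breakpoint age in years (default 60).
#' @param n_subjects subjects (one exam each).
#' @param seed RNG seed.
#' @return A [scenario_config()].
#' @export
scenario_step <- function(level_young = 0.8, level_old = 0.1,
                          breakpoint = 60, n_subjects = 30000, seed = 1L) {
  cfg <- scenario_single_factor(n_subjects = n_subjects, seed = seed)
  cfg$baseline <- c(intercept = stats::qlogis(0.06), slope = 0)
  cfg$profiles <- list(systolic_bp = beta_profile(
    "step", levels = c(level_young, level_old), breakpoints = breakpoint))
  cfg
}
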