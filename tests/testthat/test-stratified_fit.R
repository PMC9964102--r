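test_that("age-group assignment uses half-open intervals and the partition is exact", {
  g <- age_groups(c(50, 60, 70))
  expect_equal(g$labels, c("under 50", "50 to 59", "60 to 69", "70 plus"))
  expect_equal(as.character(assign_age_group(c(49, 50, 59.9, 60, 70, 95), g)),
               c("under 50", "50 to 59", "50 to 59", "60 to 69", "70 plus",
                 "70 plus"))
  coh <- tiny_cohort()
  parts <- split_by_age(coh, g)
  expect_equal(names(parts), g$labels)
  expect_equal(sum(vapply(parts, nrow, 0L)), nrow(coh))
  expect_equal(sort(unlist(lapply(parts, `[[`, "subject_id"))),
               sort(coh$subject_id), ignore_attr = TRUE)
  # degenerate: empty cohort still yields the full partition
  empty <- split_by_age(coh[0, ], g)
  expect_equal(names(empty), g$labels)
  expect_true(all(vapply(empty, nrow, 0L) == 0L))
})

test_that("standardize_factor is the affine map and rejects bad scales", {
  expect_equal(standardize_factor(c(5, 5, 5), center = 5, scale = 2),
               c(0, 0, 0))
  x <- c(1, 2, 3)
  expect_identical(standardize_factor(x, 0, 1), x)
  z <- standardize_factor(x, mean(x), sd(x))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_error(standardize_factor(x, 0, 0), "scale")
  expect_error(standardize_factor(x, 0, -1), "scale")
})

test_that("logistic fit on a saturated 2x2 design equals the closed-form log odds ratio", {
  # a=10 exposed cases, b=5 exposed controls, c=4 unexposed cases,
  # d=20 unexposed controls
  a <- 10; b <- 5; cc <- 4; d <- 20
  dat <- data.frame(
    x = rep(c(1, 1, 0, 0), c(a, b, cc, d)),
    stroke_within_window = rep(c(1, 0, 1, 0), c(a, b, cc, d)))
  fit <- fit_single_factor_logistic(dat, risk_factor_spec("x", "categorical"))
  expect_equal(fit$coefficient, log(a * d / (b * cc)), tolerance = 1e-7)
  expect_equal(fit$std_error, sqrt(1 / a + 1 / b + 1 / cc + 1 / d),
               tolerance = 1e-7)
  expect_equal(fit$n, a + b + cc + d)
  expect_equal(fit$n_events, a + cc)
  expect_true(fit$converged)
})

test_that("Wald p-value is the two-sided normal tail and matches published rounding", {
  # published under-50 systolic row: coefficient 0.70, SE 0.153, p 4.52e-6;
  # recomputing from the two-decimal inputs gives the same order of magnitude
  p <- 2 * pnorm(-abs(0.70 / 0.153))
  expect_lt(abs(p - 4.52e-6), 1.5e-6)
  # and the fit reports exactly this construction
  set.seed(2)
  dat <- data.frame(x = rnorm(400),
                    stroke_within_window = rbinom(400, 1, 0.3))
  fit <- fit_single_factor_logistic(dat, risk_factor_spec("x", "continuous"))
  expect_equal(fit$p_value,
               2 * pnorm(-abs(fit$coefficient / fit$std_error)))
})

test_that("rescaling the predictor rescales the slope and leaves the z-score unchanged", {
  set.seed(3)
  dat <- data.frame(x = rnorm(500, 120, 15),
                    stroke_within_window = rbinom(500, 1, 0.2))
  f1 <- fit_single_factor_logistic(dat, risk_factor_spec("x", "continuous"),
                                   center = 0, scale = 1)
  f2 <- fit_single_factor_logistic(dat, risk_factor_spec("x", "continuous"),
                                   center = 0, scale = 10)
  expect_equal(f2$coefficient, 10 * f1$coefficient, tolerance = 1e-6)
  expect_equal(f2$coefficient / f2$std_error, f1$coefficient / f1$std_error,
               tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  dat <- data.frame(x = rep(1, 10), stroke_within_window = rep(c(0, 1), 5))
  expect_error(fit_single_factor_logistic(dat, risk_factor_spec("x", "categorical")),
               "degenerate predictor")
  dat2 <- data.frame(x = rnorm(10), stroke_within_window = rep(0, 10))
  expect_error(fit_single_factor_logistic(dat2, risk_factor_spec("x", "continuous")),
               "at least one case")
})

test_that("complete separation is flagged as non-converged with unavailable SE", {
  dat <- data.frame(x = c(rep(0, 10), rep(1, 10)),
                    stroke_within_window = c(rep(0, 10), rep(1, 10)))
  fit <- fit_single_factor_logistic(dat, risk_factor_spec("x", "categorical"))
  expect_false(fit$converged)
  expect_true(is.na(fit$std_error))
  expect_true(is.na(fit$p_value))
})

test_that("pooled scaling gives identical predictor units across age groups", {
  set.seed(6)
  coh <- generate_cohort(scenario_config(n_subjects = 2500, seed = 6))
  design <- suppressWarnings(select_matched_controls(coh, match_config(seed = 2)))
  fits <- fit_stratified(design, default_risk_factors()["systolic_bp"])
  expect_equal(nrow(fits), 4L)
  expect_equal(length(unique(fits$center)), 1L)
  expect_equal(length(unique(fits$scale)), 1L)
  expect_equal(attr(fits, "scaling"), "pooled")
  # n/n_events bookkeeping
  expect_true(all(fits$n_events <= fits$n))
  expect_true(all(fits$p_value > 0 & fits$p_value <= 1, na.rm = TRUE))
})

test_that("estimates are consistent: large-n single-factor recovery within 3 SE", {
  coh <- generate_cohort(scenario_single_factor(beta = 0.5,
                                                n_subjects = 20000,
                                                seed = 14))
  ref <- attr(coh, "truth")$reference_scaling
  i <- ref$factor == "systolic_bp"
  fit <- fit_single_factor_logistic(coh, risk_factor_spec("systolic_bp", "continuous"),
                                    center = ref$center[i], scale = ref$scale[i])
  expect_lt(abs(fit$coefficient - 0.5), 3 * fit$std_error)
})
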