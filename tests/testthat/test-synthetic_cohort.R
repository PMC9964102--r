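test_that("beta profiles evaluate their functional forms", {
  expect_equal(eval_beta_profile(beta_profile("constant", value = 0.5),
                                 c(30, 54.5, 90)), rep(0.5, 3))
  expect_equal(eval_beta_profile(beta_profile("linear", intercept = 0,
                                              slope = 0.01), 54.5), 0.545)
  st <- beta_profile("step", levels = c(0.5, 0.1), breakpoints = 60)
  expect_equal(eval_beta_profile(st, c(59, 60)), c(0.5, 0.1))
  q <- beta_profile("quadratic", a = 1, b = -0.02, c = 1e-4)
  expect_equal(eval_beta_profile(q, 50), 1 - 1 + 0.25)
  expect_true(is_proportional_truth(beta_profile("constant", value = 1)))
  expect_true(is_proportional_truth(beta_profile("linear", intercept = 0,
                                                 slope = 1)))
  expect_false(is_proportional_truth(st))
  expect_error(beta_profile("spline"))
  expect_error(beta_profile("step", levels = c(1, 2), breakpoints = c(70, 60)))
})

test_that("invalid scenario configurations fail before any sampling", {
  expect_error(scenario_config(n_subjects = 0))
  expect_error(scenario_config(missing_rate = 1.5))
  expect_error(scenario_config(age_range = c(90, 30)))
  expect_error(scenario_config(
    profiles = list(systolic_bp = beta_profile("step", levels = c(1, 0),
                                               breakpoints = 95))),
    "age range")
})

test_that("generation is deterministic from the seed and schema-conformant", {
  cfg <- scenario_config(n_subjects = 400, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(scenario_config(n_subjects = 400, seed = 78))
  expect_false(identical(a, c2))

  # write/read round trip through the cohort schema
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, path)
  back <- read_cohort(path)
  expect_equal(back$systolic_bp, a$systolic_bp, tolerance = 1e-9)

  # downstream modules accept generated cohorts unchanged
  expect_silent(suppressMessages(apply_missingness_rules(a)))
  expect_equal(flag_outcomes(a, cfg$window_years)$stroke_within_window,
               a$stroke_within_window)
  fits <- fit_stratified(suppressWarnings(
    select_matched_controls(a, match_config(seed = 1))),
    default_risk_factors()["systolic_bp"])
  expect_equal(nrow(fits), 4L)
})

test_that("empirical event rate matches the configured baseline", {
  # zero effects and a flat baseline at 5%: the event indicator is
  # Bernoulli(0.05) exactly, so the empirical rate obeys the binomial bound
  cfg <- scenario_config(n_subjects = 100000, exams_per_subject = 1,
                         baseline = c(intercept = qlogis(0.05), slope = 0),
                         profiles = list(), seed = 123)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 100000)
  expect_lt(abs(mean(coh$stroke_within_window) - 0.05),
            3 * sqrt(0.05 * 0.95 / 100000))
})

test_that("with zero effects cases and controls have exchangeable factors", {
  cfg <- scenario_config(n_subjects = 20000, exams_per_subject = 1,
                         baseline = c(intercept = qlogis(0.05), slope = 0),
                         profiles = list(), seed = 321)
  coh <- generate_cohort(cfg)
  # age drift exists in both arms equally; compare age-adjusted residuals
  res <- resid(lm(systolic_bp ~ age, data = coh))
  p <- t.test(res[coh$stroke_within_window == 1],
              res[coh$stroke_within_window == 0])$p.value
  expect_gt(p, 0.001)
})

test_that("repeated exams age forward and stop at the first stroke", {
  cfg <- scenario_config(n_subjects = 500, exams_per_subject = c(3, 3),
                         exam_spacing = 2, seed = 9)
  coh <- generate_cohort(cfg)
  by_subj <- split(coh, coh$subject_id)
  ages_ok <- vapply(by_subj, function(d)
    all(diff(d$age) == cfg$exam_spacing), logical(1))
  expect_true(all(ages_ok))
  # at most one flagged exam per subject, and always the last one emitted
  flag_ok <- vapply(by_subj, function(d) {
    s <- sum(d$stroke_within_window)
    s <= 1 && (s == 0 || which(d$stroke_within_window == 1) == nrow(d))
  }, logical(1))
  expect_true(all(flag_ok))
})

test_that("truth manifest records profiles and reference scalings", {
  coh <- generate_cohort(scenario_step(seed = 3, n_subjects = 200))
  truth <- attr(coh, "truth")
  expect_equal(truth$profiles$systolic_bp$mode, "step")
  expect_true(all(c("factor", "center", "scale") %in%
                  names(truth$reference_scaling)))
  expect_equal(truth$seed, 3)
})

test_that("a single-replicate operating-characteristics run summarises one outcome", {
  oc <- run_operating_characteristics(
    scenario_null(n_subjects = 2500, seed = 1), n_reps = 1, seed = 5)
  expect_equal(oc$n_reps, 1L)
  expect_true(all(oc$rates$n <= 1))
  expect_true(all(oc$rates$rate %in% c(0, 1)))
  expect_true(all(oc$rates$conf_low <= oc$rates$rate &
                  oc$rates$rate <= oc$rates$conf_high))
})
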