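test_that("z_statistic evaluates the coefficient-difference formula", {
  expect_equal(z_statistic(1.0, 0.1, 0.5, 0.1), 0.5 / sqrt(0.02),
               tolerance = 1e-12)
  expect_equal(z_statistic(0.7, 0.2, 0.7, 0.05), 0)
  # published pairs, recomputed from two-decimal inputs
  expect_equal(z_statistic(0.70, 0.153, 0.17, 0.037), 3.37, tolerance = 0.05)
  expect_equal(abs(z_statistic(0.48, 0.523, 2.64, 0.155)), 3.97,
               tolerance = 0.05)
  expect_error(z_statistic(1, 0, 2, 0.1), "positive")
  expect_error(z_statistic(1, -0.1, 2, 0.1), "positive")
})

test_that("z_statistic is antisymmetric in the pair ordering", {
  set.seed(10)
  for (i in 1:25) {
    b <- rnorm(2); se <- runif(2, 0.01, 1)
    expect_equal(z_statistic(b[1], se[1], b[2], se[2]),
                 -z_statistic(b[2], se[2], b[1], se[1]), tolerance = 1e-12)
  }
})

test_that("pair enumeration is exhaustive: k(k-1)/2 pairs", {
  for (k in c(2, 3, 4, 5)) {
    fits <- make_fits(seq_len(k) / 10, rep(0.1, k),
                      groups = paste("g", seq_len(k)))
    pairs <- enumerate_group_pairs(fits)
    expect_equal(nrow(pairs), choose(k, 2))           # 6 for k=4, 10 for k=5
    expect_equal(nrow(unique(pairs[, c("i", "j")])), nrow(pairs))
  }
  expect_error(enumerate_group_pairs(make_fits(0.5, 0.1, groups = "g1")),
               "fewer than 2")
})

test_that("primary pair attains the maximum |difference| (exhaustive oracle)", {
  # worked example: coefficients 0.5, 0.51, 0.7 -> test 0.5 vs 0.7
  fits <- make_fits(c(0.5, 0.51, 0.7), c(0.1, 0.01, 0.2),
                    groups = c("g1", "g2", "g3"))
  p <- select_primary_pair(fits)
  expect_equal(c(p$group1, p$group2), c("g1", "g3"))

  # random instances against a brute-force argmax
  set.seed(20)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    fits <- make_fits(round(rnorm(k), 2), runif(k, 0.02, 0.5),
                      groups = paste("g", seq_len(k)))
    p <- select_primary_pair(fits)
    best <- max(abs(outer(fits$coefficient, fits$coefficient, "-")))
    expect_equal(abs(fits$coefficient[p$i] - fits$coefficient[p$j]), best)
  }

  # published sex row: (0.22, 0.06, -0.08, 0.15) -> under 50 vs 60 to 69
  sex <- make_fits(c(0.22, 0.06, -0.08, 0.15), c(0.271, 0.155, 0.100, 0.074))
  p <- select_primary_pair(sex)
  expect_equal(c(p$group1, p$group2), c("under 50", "60 to 69"))

  # all-equal coefficients: tie resolves to the youngest-anchored, widest pair
  eq <- make_fits(rep(0.4, 4), c(0.1, 0.2, 0.3, 0.4))
  p <- select_primary_pair(eq)
  expect_equal(p$group1, "under 50")
  expect_equal(p$group2, "70 plus")
})

test_that("secondary pair is SE-gated exactly as the worked examples", {
  fits <- make_fits(c(0.5, 0.51, 0.7), c(0.1, 0.01, 0.2),
                    groups = c("g1", "g2", "g3"))
  primary <- select_primary_pair(fits)
  s <- select_secondary_pair(fits, primary)
  expect_equal(c(s$group1, s$group2), c("g2", "g3"))   # 0.51 vs 0.7

  fits2 <- make_fits(c(0.5, 0.51, 0.7), c(0.1, 0.3, 0.2),
                     groups = c("g1", "g2", "g3"))
  expect_null(select_secondary_pair(fits2, select_primary_pair(fits2)))

  # published high-blood-pressure-treatment row: secondary is 60-69 vs 70+
  hbp <- make_fits(c(0.66, 0.21, 0.23, 0.11), c(0.460, 0.201, 0.104, 0.074))
  s <- select_secondary_pair(hbp, select_primary_pair(hbp))
  expect_equal(c(s$group1, s$group2), c("60 to 69", "70 plus"))
})

test_that("magnitude test tiers and stops per the two-test protocol", {
  crit10 <- qnorm(0.95)
  # strongly significant primary: one test only
  sys <- make_fits(c(0.70, 0.54, 0.50, 0.17), c(0.153, 0.081, 0.053, 0.037))
  cmp <- magnitude_difference_test(sys)
  expect_equal(nrow(cmp$tested_pairs), 1L)
  expect_equal(cmp$tier, "significant_5")

  # 10%-tier primary: no secondary test either
  chol <- make_fits(c(0.36, 0.16, 0.17, 0.07), c(0.143, 0.090, 0.063, 0.050))
  cmp <- magnitude_difference_test(chol)
  expect_equal(nrow(cmp$tested_pairs), 1L)
  expect_equal(cmp$tier, "significant_10")
  expect_true(abs(cmp$tested_pairs$Z[1]) < qnorm(0.975))
  expect_true(abs(cmp$tested_pairs$Z[1]) >= crit10)

  # non-significant primary with an eligible secondary: two tests, still "no"
  hbp <- make_fits(c(0.66, 0.21, 0.23, 0.11), c(0.460, 0.201, 0.104, 0.074))
  cmp <- magnitude_difference_test(hbp)
  expect_equal(nrow(cmp$tested_pairs), 2L)
  expect_equal(cmp$tier, "not_significant")
  expect_true(any(grepl("secondary", cmp$rule_trace)))

  # non-significant primary, secondary lifts the factor to the 10% tier
  sex <- make_fits(c(0.22, 0.06, -0.08, 0.15), c(0.271, 0.155, 0.100, 0.074))
  cmp <- magnitude_difference_test(sex)
  expect_equal(nrow(cmp$tested_pairs), 2L)
  expect_equal(cmp$tier, "significant_10")
})

test_that("significance pattern flags change across groups", {
  hbp <- make_fits(c(0.66, 0.21, 0.23, 0.11), c(0.460, 0.201, 0.104, 0.074),
                   p_values = c(0.15, 0.31, 0.03, 0.15))
  pat <- significance_pattern(hbp, 0.05)
  expect_equal(unname(pat$flags), c(FALSE, FALSE, TRUE, FALSE))
  expect_true(pat$changed)

  bmi <- make_fits(c(0.32, 0.32, 0.06, 0.06), c(0.136, 0.078, 0.050, 0.037),
                   p_values = c(0.02, 4.03e-5, 0.27, 0.12))
  pat <- significance_pattern(bmi, 0.05)
  expect_equal(unname(pat$flags), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(pat$changed)

  allsig <- make_fits(c(0.3, 0.4), c(0.1, 0.1), p_values = c(0.01, 0.001),
                      groups = c("g1", "g2"))
  expect_false(significance_pattern(allsig, 0.05)$changed)
})

test_that("step-2 verdict combines magnitude tier and significance change", {
  sys <- make_fits(c(0.70, 0.54, 0.50, 0.17), c(0.153, 0.081, 0.053, 0.037),
                   p_values = c(4.52e-6, 4e-11, 2e-16, 2.27e-6))
  v <- step2_verdict(magnitude_difference_test(sys),
                     significance_pattern(sys))
  expect_true(v$proceed_to_step3)
  expect_false(v$pattern_consulted)   # settled at the 5% tier

  hbp <- make_fits(c(0.66, 0.21, 0.23, 0.11), c(0.460, 0.201, 0.104, 0.074),
                   p_values = c(0.15, 0.31, 0.03, 0.15))
  v <- step2_verdict(magnitude_difference_test(hbp),
                     significance_pattern(hbp))
  expect_equal(v$magnitude_tier, "not_significant")
  expect_true(v$significance_changed)
  expect_true(v$proceed_to_step3)

  flat <- make_fits(c(0.30, 0.31, 0.29, 0.30), c(0.3, 0.3, 0.3, 0.3),
                    p_values = c(0.3, 0.3, 0.3, 0.3))
  v <- step2_verdict(magnitude_difference_test(flat),
                     significance_pattern(flat))
  expect_false(v$proceed_to_step3)

  other <- make_fits(c(0.3, 0.4), c(0.1, 0.1), p_values = c(0.01, 0.02),
                     factor = "other", groups = c("g1", "g2"))
  expect_error(step2_verdict(magnitude_difference_test(hbp),
                             significance_pattern(other)),
               "different factors")
})
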