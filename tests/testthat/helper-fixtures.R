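# Small in-code fixtures shared across tests.

# minimal well-formed cohort with explicit times (decimal years)
tiny_cohort <- function() {
  data.frame(
    subject_id = c("a", "a", "b", "c", "d", "e"),
    exam_time = c(0, 6, 0, 0, 0, 0),
    age = c(45, 51, 55, 62, 71, 48),
    systolic_bp = c(120, 130, 140, 150, 160, 125),
    diastolic_bp = c(80, 82, 85, 88, 90, 81),
    total_cholesterol = c(180, 190, 200, 210, 220, 185),
    bmi = c(24, 25, 27, 28, 29, 23),
    sex = c(0, 0, 1, 0, 1, 1),
    atrial_fibrillation = c(0, 0, 0, 1, 1, 0),
    hbp_treatment = c(0, 0, 1, 0, 1, 0),
    cvd_status = c(0, 0, 0, 1, 1, 0),
    stroke_within_window = c(0, 0, 1, 0, 1, 0),
    first_stroke_time = c(5, 5, 2, NA, 3, NA),
    stringsAsFactors = FALSE)
}

# per-factor fit table built from explicit numbers, in age order
make_fits <- function(coefficients, std_errors,
                      p_values = rep(0.5, length(coefficients)),
                      factor = "x",
                      groups = c("under 50", "50 to 59", "60 to 69",
                                 "70 plus")[seq_along(coefficients)]) {
  data.frame(factor = factor, group = groups, coefficient = coefficients,
             std_error = std_errors, p_value = p_values,
             n = NA_integer_, n_events = NA_integer_, converged = TRUE,
             center = 0, scale = 1, stringsAsFactors = FALSE)
}

# a cohort where exact 1:2 matching is guaranteed: each case has many
# same-age, same-cvd controls
matched_ready_cohort <- function(n_cases = 3, controls_per_age = 10,
                                 ages = c(45, 55, 65)) {
  stopifnot(n_cases <= length(ages))
  cases <- data.frame(
    subject_id = sprintf("case%02d", seq_len(n_cases)),
    exam_time = 0, age = ages[seq_len(n_cases)],
    cvd_status = 0, stroke_within_window = 1,
    stringsAsFactors = FALSE)
  ctrl_age <- rep(ages, each = controls_per_age)
  controls <- data.frame(
    subject_id = sprintf("ctrl%03d", seq_along(ctrl_age)),
    exam_time = 0, age = ctrl_age,
    cvd_status = 0, stroke_within_window = 0,
    stringsAsFactors = FALSE)
  rbind(cases, controls)
}
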