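---
title: "Methods: testing whether risk factors are proportional to age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing whether risk factors are proportional to age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageprop)
```

## The problem

Age dominates most stroke risk scores: it is such a strong predictor that it
can mask how the *other* risk factors behave. If a factor's contribution to
risk keeps a constant ratio with age, its effect can be absorbed by an age
term or an age interaction. If it does not — if, say, systolic blood
pressure matters much more at 45 than at 80 — then a single model with age
as a covariate will systematically mis-rank individuals in some age bands.
`ageprop` implements a three-step screening framework for deciding, factor
by factor, whether there is evidence of such non-proportionality in models
that predict an event *within a time window* (here, a first ischemic stroke
within five years), where the proportional-hazards machinery of survival
analysis does not directly apply.

The three steps are:

1. **Stratified fits.** Split the exam-level data into predefined age
   groups (default: under 50, 50–59, 60–69, 70 plus) and fit, per risk
   factor and group, a single-variable logistic regression of the
   within-window outcome on that factor alone.
2. **Coefficient comparison.** For each factor, test whether its
   coefficients differ across groups, using the z statistic for the
   difference of two independent regression coefficients,
   \(Z = (b_1 - b_2) / \sqrt{SE_{b_1}^2 + SE_{b_2}^2}\),
   with a deliberately minimal testing protocol (below). If magnitudes do
   not differ, check whether the *significance* of the coefficient changes
   across groups.
3. **Proportionality.** For factors that show a change, plot coefficient
   against an age coordinate per group and ask whether the relationship is
   linear. A linear relationship is consistent with proportionality; a
   non-linear one is not.

## Step 1: stratified single-variable fits

Each fit is an intercept-plus-one-predictor binomial GLM, estimated by
iteratively reweighted least squares with a relative-deviance tolerance of
1e-10 and at most 100 iterations. Standard errors are Wald standard errors
from the inverse information at the optimum (observed and expected
information coincide for the canonical logit link), and p-values use the
two-sided normal reference, the usual Wald practice in logistic
regression.

**Predictor scaling.** Cross-group comparison requires coefficients in
identical units. The default (`scaling = "pooled"`) z-scores each
continuous factor by the mean and SD of the *whole* design set, so a
coefficient is the log-odds change per pooled SD in every group. This is
the most consequential open choice in the framework: standardizing within
group (`"group"`) changes what is compared when factor variances drift
with age, and no scaling (`"none"`) leaves mmHg/mg/dL/kg·m^-2 units.
All three (plus `"manual"`) are available; the scaling used is recorded in
every fit row.

Degenerate inputs are explicit: a constant predictor is an error
("degenerate predictor"), a stratum with no cases or no controls is an
error, and complete separation yields a non-converged row with `NA`
standard error that downstream steps exclude rather than propagate.

## Step 2: the comparison protocol

The testing protocol is intentionally minimal — one difference suffices to
show that coefficients change, and fewer tests mean less multiple-testing
inflation (no Bonferroni correction is applied, trading a larger type-I
error for a smaller type-II error; a false positive here still has to
survive step 3, whereas a false negative is never looked at again):

* **Primary pair.** Test the pair of groups with the largest absolute
  coefficient difference. With coefficients reported to two decimals,
  exact ties are common; ties resolve to the pair anchored at the youngest
  group, then the widest age separation, then the smaller standard-error
  sum. (This tie-break reproduces the published case-study table this
  package ships; ranking tied pairs by standard error first does not.)
* **Secondary pair.** Only if the primary test is not significant even at
  the 10% level, and only if some remaining pair has a *strictly smaller*
  sum of standard errors than the primary pair, test the best such pair —
  the one with the largest coefficient difference within that
  better-powered set. At most two tests are ever run per factor.
  (Describing the candidate as the "second-largest difference" does not
  match the published table's own second rows; the smaller-SE-sum rule
  implemented here does, and the `rule_trace` notes the distinction on
  every run.)
* **Tiers.** Two-sided normal critical values: 1.959964 (5%) and
  1.644854 (10%). The factor's tier is the best tier over its tested
  pairs.
* **Significance-pattern fallback.** For factors not settled at the 5%
  tier, compare each group's Wald p-value to the 5% level (10% flags are
  also reported); if some groups are significant and others are not, the
  factor's importance changes with age even without a demonstrated
  magnitude difference. A factor proceeds to step 3 when either the
  magnitude tier or the pattern shows a change.

## Step 3: proportionality as linearity

Each group is placed at an age coordinate: bounded decade groups use the
integer-age midpoint ((50 + 59)/2 = 54.5 — the convention for a group
whose recorded ages run 50–59, not the interval midpoint 55), and the
open-ended youngest/oldest groups use the median observed age in the
group, or an explicit override (there is no midpoint for "70 plus"; the
median is data-driven and robust to the age tail).

The published framework judges linearity visually. A visual test cannot be
rerun by a machine, so the package adds a quantitative surrogate while
still emitting the plot: a line is fitted through the (age, coefficient)
points by weighted least squares with weights \(1/SE^2\), and the
lack-of-fit statistic \(\sum_i (b_i - \hat b_i)^2 / SE_i^2\) is referred
to a chi-square with (points − 2) degrees of freedom — the standard
fixed-effect meta-regression heterogeneity statistic, here applied across
age groups. The verdict is *non-proportional* when the lack-of-fit
p-value is below the level (default 0.05), *proportional* otherwise, and
*indeterminate* with two points (a line always fits two points; reporting
"proportional" there would be vacuous). The unweighted variant (OLS line,
same standardized residual statistic) is computed alongside because the
published plots show point estimates only; the weighted version is the
default since group SEs differ by an order of magnitude in practice.
Because fitted lines are invariant under affine maps of the x axis, the
statistic does not depend on how age is re-coordinatized — only on which
coordinate each group gets.

## The matched design

The modelling set is deliberately unbalanced-corrected: every case exam
(stroke within the window) is kept, and two control exams per case are
drawn without replacement from exams with no stroke in the window, matched
on cardiovascular disease status and age, within the same age group, so
the 1:2 ratio holds within every group. "Matched on age" is
operationalized as an exact (0-year) caliper widened in 1-year steps up to
3 years when a case has too few exact-age controls — deterministic,
auditable (every widening is in the match report), and graceful in sparse
strata. Cases are processed in sorted (subject, exam time) order so the
greedy draw is reproducible given the seed; a subject's other exams are
never used as controls for their own case exam; matching is without
replacement, so a control serves at most one case. Unmatched remainder is
a warning (or an error under `strict`), never silent.

## Missing data and outcome flagging

Exams missing any continuous factor are dropped; a missing categorical
factor is recoded to its reference level — for condition/treatment
indicators, a missing value is read as "does not have the condition".
Unparseable numeric cells in input CSVs become missing rather than fatal
so these rules can act on them. Outcome flagging uses the half-open
window \((0, w]\): a stroke exactly at five years counts as "within five
years", and exams at or after a subject's first stroke are excluded (the
framework concerns first strokes). Flagging is idempotent.

## The synthetic test bed

The cohort data behind the packaged case-study table are request-only, so
the package carries a generator that emulates their *structure*, not their
numbers: exam-level records with repeated exams per subject (1–3 exams,
two years apart, factor values re-drawn around the aged-forward mean),
seven risk factors with mildly age-drifting distributions, a
cardiovascular-disease indicator for matching, and a five-year outcome
drawn per exam as Bernoulli(logistic(α(age) + Σ β_f(age)·x_f)), with
continuous factors entering on a fixed reference standardization recorded
in the truth manifest. The default baseline −4.5 + 0.05·(age − 60)
log-odds yields an event rate of a few percent, rising with age, which is
the realistic regime for five-year first-stroke risk. Effect profiles per
factor are `constant` or `linear` (proportional truths) and `step` or
`quadratic` (non-proportional truths). Exams after a subject's first
within-window stroke are not emitted, so the generated table is internally
consistent under re-flagging.

What the generator does *not* emulate: within-subject outcome correlation
(outcomes are independent across a subject's exams, matching the
framework's own treatment of repeated exams as independent rows),
measurement error, cohort effects, competing risks (e.g., death), and any
calibration to real summary statistics. Passing tests on this test bed
therefore show that the *procedure* behaves as designed under its own
assumptions — not that those assumptions hold in any particular cohort.

Three named scenarios fix the study conditions used to characterize the
procedure; all three use an age-flat baseline and an age-flat factor
distribution so that the estimand is exactly the configured effect, with
no confounding by age:

* `scenario_single_factor()` — constant β = 0.5, 20,000 single-exam
  subjects: checks that stratum-free fits recover the truth (the reported
  interval ±3 SE should cover β in ≈ 99.7% of replicates; the acceptance
  suite requires ≥ 99% over 200 replicates).
* `scenario_null()` — identical true coefficients in all groups, 3,000
  subjects: any step-2 detection is a false positive. Because the tested
  pair is *selected* as the most extreme of the 6 candidate pairs, the
  empirical rejection rate at the nominal 5% level sits well above 5% —
  the selection inflation the protocol knowingly accepts; the
  operating-characteristics summary reports it with an exact binomial
  confidence interval.
* `scenario_step()` — effect 0.8 below age 60 and 0.1 at or above,
  30,000 subjects: a strongly non-proportional truth. The size was set by
  a design-time power calculation: at the resulting matched-design sizes
  the per-group SEs are ≈ 0.06–0.08, giving a lack-of-fit noncentrality
  around 30 and step-3 power near 1, so the detection rate over
  replicates is required to exceed 0.9 with margin.

`run_operating_characteristics()` replays generate → match → fit →
step 2 → step 3 over independent replicates (per-replicate seeds drawn
once from the master seed, so any replicate can be reproduced alone) and
reports per-factor detection/verdict rates with exact binomial intervals;
replicate-level failures are counted and excluded rather than fatal.

## Numerical and design choices

* Critical values are normal, not t — consistent with Wald logistic
  practice and with the published tiering of the case-study table.
* The case-study table ships with the package at two-decimal precision;
  z statistics recomputed from it differ from the published ones by up to
  ≈ 0.03 (the original analysis evidently used unrounded coefficients).
  Two of its p-values are published only as "< 2e-16" and are stored at
  that bound, which the significance flags are insensitive to.
* Matching defaults (with/without replacement, caliper) are unstated in
  the source analysis; the defaults here (without replacement, exact age
  then ≤ 3-year caliper, no self-matching) are the conservative choices
  and all are configuration-exposed.
* Repeated exams per subject enter as independent rows by design; a
  sensitivity analysis restricting to one exam per subject can be done by
  filtering the cohort before the run.
* All tabular outputs are plain CSV with JSON twins at 10 significant
  digits; the run manifest records the configuration, seed and package
  version needed to re-execute a run.

## Worked example on the packaged case-study table

Steps 2–3 run directly on the published fit table; the open-ended groups
need explicit age coordinates because no individual-level ages are
available:

```{r example}
run <- run_framework(
  fits = stroke_case_study(),
  config = framework_config(age_coordinates = c("under 50" = 44.5,
                                                "70 plus" = 76)))
run$step2$summary[, c("factor", "group1", "group2", "Z", "significant")]
run$step3$summary[, c("factor", "statistic", "p_value", "verdict")]
```

Three factors (systolic blood pressure, diastolic blood pressure, atrial
fibrillation) show a 5%-level magnitude difference; total cholesterol and
BMI reach the 10% tier; sex reaches it only through the secondary,
better-powered pair; high-blood-pressure treatment shows no magnitude
difference but a significance change (only the 60–69 group is significant
at 5%). All seven proceed to step 3.

The step-3 outcome is instructive: at the default 5% level the weighted
lack-of-fit statistic flags *none* of the seven factors — with four
points, two residual degrees of freedom and the published standard
errors, the visible wiggles in the coefficient-versus-age plots are
within what coefficient uncertainty alone can produce. The original
visual reading of the same points called five factors non-linear, but a
visual judgment does not weight by uncertainty (the plots show point
estimates only). The package reports both — the statistic and the plot —
side by side rather than reconciling them; the divergence is itself the
argument for a reproducible, uncertainty-aware surrogate for the visual
check.

## Known limitations

* Four age groups give two degrees of freedom for the lack-of-fit test:
  power against smooth-but-curved alternatives is limited, and the verdict
  is about detectable non-linearity, not functional form.
* The selection of the extreme pair inflates step-2 type-I error above
  the nominal level by design; users who need calibrated family-wise
  error should interpret tiers as screening flags, not confirmatory
  p-values.
* Unconditional logistic fits on an age-matched case-control set estimate
  factor effects consistently but not baseline risk; the framework never
  interprets intercepts.
* The generator's independence assumptions (across subjects and across a
  subject's exams) understate real within-subject correlation; simulated
  operating characteristics are in that sense optimistic about effective
  sample size.
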