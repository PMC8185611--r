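---
title: "Methods: trial-based cost-effectiveness analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## The evaluation problem

`trialcea` implements the health-economic evaluation of a pragmatic
two-arm randomized trial: a guided internet-delivered cognitive
behavioural therapy for insomnia (iCBT-I) offered to employed
schoolteachers with clinically significant insomnia, against a
wait-list control, both with unrestricted access to usual care.
Assessments fall at baseline, posttreatment (8 weeks) and 6 months; the
horizon is 0.5 years, so costs and effects are not discounted.

Two questions are asked jointly: *cost-effectiveness* — euros per
additional symptom-free participant (Insomnia Severity Index < 8 at 6
months) — and *cost–utility* — euros per QALY gained, where QALYs are
the trapezoid area under linearly interpolated SF-6D utilities.
Utilities are inputs to the pipeline: the published Brazier tariff that
maps SF-12 responses to utilities is deliberately out of scope, and the
generator uses a simple truncated-normal/linear-trajectory model
instead (clearly not a tariff).

Each analysis is run from two perspectives. The *societal* perspective
sums all cost categories; the *public health care* perspective keeps
only direct medical costs (programme fee, GP, mental-health care,
medication, allied health).

## Costing model

Resource use is recorded per recall window (default two 3-month
windows, mirroring a 3-month-recall questionnaire; the number of
windows is configurable because the administration schedule over the
6-month horizon is an assumption, not a datum). Valuation rules, all
exposed as unit operations:

| Category | Rule | Default price |
|---|---|---|
| GP / specialist / inpatient | count × unit price | €20.92 GP visit, €46.55 psychiatrist, €81.44 psychotherapist, €335.52 / €306.41 inpatient day |
| Medication | defined daily doses × weighted price | statutory share 0.89 weighting statutory vs private price |
| Travel | km × rate | €0.30/km |
| Informal care | hours × opportunity cost | €23.10/h |
| Domestic help | hours × replacement cost | €18.33/h |
| Absenteeism | workdays × gross daily wage | participant wage (human capital approach) |
| Presenteeism (main) | impaired days × inefficiency × wage | Osterhaus method |
| Presenteeism (sensitivity) | recoverable hours × hourly wage | HLQ method |

Prices are indexed to the 2013 reference year with a consumer-price
factor of 1.04 and converted to pound sterling at purchasing power
parity €1 = £0.85. The two hourly rates are listed without a fully
explicit per-category assignment in the source material; the package
assigns opportunity cost to informal care and replacement cost to
domestic help, and both assignments are configurable arguments of
`cost_patient_family()`. The exact HLQ computation is likewise not
spelled out in the methodological literature at the level of an
algorithm; the implemented form — recoverable, not-yet-compensated
hours times the gross hourly wage — follows the method's description
and is flagged here as an interpretation. Internal arithmetic is kept
at full precision; rounding (half away from zero; two decimals for unit
prices, whole currency units for aggregates) happens only at reporting.

## Statistical model

Incremental costs and effects are arm coefficients of regression
models, adjusted for baseline imbalance:

* cost equation: `cost ~ arm + age + baseline_depression`. For point
  estimation a gamma-family GLM with identity link is available
  (`fit_cost_model()`), the family being checkable with the modified
  Park test (slope of log squared residuals on log fitted values; 2 ≈
  gamma). Since the gamma likelihood is undefined at zero, zero costs
  are floored at €0.01, and the fit falls back to gaussian when more
  than 20% of costs are zero.
* effect equation: `effect ~ arm + utility_t0` for QALYs (baseline
  adjustment by regression, not subtraction), `effect ~ arm` for
  symptom-free status (linear probability model; the arm coefficient is
  the adjusted risk difference).

For uncertainty, the two equations are estimated jointly as seemingly
unrelated regressions (`sur_fit()`): feasible generalized least squares
on the stacked system with a free 2×2 residual covariance, iterated to
convergence. When both equations share a regressor set, FGLS provably
reduces to per-equation OLS, which the tests exploit as an exact
oracle. If an equation fits perfectly (zero residual variance, as in
degenerate duplicated-row data) the GLS weighting is undefined and the
OLS solution — which is then exact — is returned; a genuinely singular
residual covariance with non-zero variances raises an error.

`bootstrap_sur()` resamples *participants* with replacement, refits the
system per resample and collects B = 2500 incremental (cost, effect)
pairs. Resamples on which the fit fails are redrawn rather than dropped
so B stays exactly 2500; more than 5% failures abort with diagnostics.
Confidence intervals for the increments are bias-corrected and
accelerated (BCa): the bias correction comes from the fraction of
replicates below the point estimate, the acceleration from the skewness
of jackknife leave-one-out estimates (the acceleration estimator is not
dictated by the source material; the jackknife is the package's
documented choice). With zero bias and acceleration the interval
reduces exactly to the percentile interval, which is tested.

Missing follow-up data (dropout ≈ 12%) are handled per scenario:
intention-to-treat analyses impute the scenario's cost and effect by
*deterministic* regression imputation — predicted means from a
least-squares fit on the union of outcome predictors and dropout
predictors (the latter screened by logistic regression of missingness
on baseline covariates at p < 0.2). A stochastic draw is deliberately
not added: the procedure mirrors single regression imputation, not
multiple imputation. Completers-only analyses drop incomplete
participants instead; requesting imputation together with a
completers-only sample is a configuration error.

## Decision analytics

From the replicate cloud, `evaluate_cloud()` derives:

* the ICER ΔC/ΔE, flagged *dominant* when ΔC < 0 and ΔE > 0 (reported
  ratios are suppressed for dominant results). The reported ICER is the
  ratio of the point estimates by default; a bootstrap
  mean-of-ratios convention is available behind a flag because the two
  can differ noticeably when ΔE is small — the source table's "mean"
  header is ambiguous between them, and the package documents rather
  than resolves that ambiguity.
* the ICER's 95% *acceptability interval*: replicates are ordered by
  their angle on the cost-effectiveness plane (a ray rotating
  counterclockwise from the south axis, so the dominant south-east
  quadrant sorts first and the dominated north-west last) and the
  interval endpoints are the ICERs of the replicates at the 2.5% and
  97.5% positions of that ordering. The angular convention is the
  package's own, tested for internal consistency at B = 100,000.
* the quadrant distribution of the plane. Boundary convention: ΔC = 0
  counts as "not more costly" (south), ΔE = 0 as "not more effective"
  (west). Exact zeros have probability zero for continuous clouds, so
  the convention is cosmetic, but it is fixed and tested.
* cost-effectiveness acceptability curves: for each willingness-to-pay
  λ on a grid (default 0–50,000 by 250 €/QALY; 0–5,000 by 50 per
  symptom-free individual), the fraction of replicates with positive
  net monetary benefit λ·ΔE − ΔC. Ties count as not cost-effective
  (conservative, measure-zero for continuous clouds).

## The synthetic cohort generator

No participant-level data are distributed with the trial, so
`generate_cohort()` emulates the study conditions and is itself
first-class, tested code. Its defaults *are* the study conditions: two
arms of 64; remission probabilities 0.42 (intervention) and 0.06
(control); baseline utility ≈ 0.70 with a linear intervention
trajectory calibrated so the mean QALY gain is 0.019 over the
half-year; 6-month cost-category means per arm equal to the trial's
cost table (with the control-arm domestic-help mean reconstructed as
€295 from the incremental column, the printed cell being garbled);
dropout 12%, missing at random given a baseline covariate, so ~88% of
follow-ups complete.

Where the source states no value the generator makes one realistic
choice and keeps it: age 48 (SD 10) truncated to working age; a
CES-D-like depressive-symptom score 18 (SD 8); gross daily wage €150
(SD 30, floored at €50), consistent with teacher salaries over ~220
working days/year; baseline ISI 15–28 (inclusion required clinically
significant symptoms); utility measurement noise SD 0.02; baseline
utilities truncated at 0.90 so the intervention trajectory stays clear
of the utility ceiling and the configured QALY gain is not attenuated;
category-specific zero-use probabilities (e.g. 85% for medication, 30%
for presenteeism); presenteeism inefficiency ~ Beta with mean 0.4; HLQ
recoverable hours fixed at 40% of the Osterhaus-equivalent hours so the
HLQ estimate is lower by construction, as the method intends.

Costs are two-part: a Bernoulli use indicator times a gamma magnitude
with coefficient of variation 1, matching the zero-heavy skewness that
motivates the gamma GLM. Resource-use quantities are then back-derived
from the drawn category cost and the unit prices (so costing the
records reproduces the drawn costs exactly, and the law-of-large-number
calibration tests are exact); quantities are therefore continuous
rather than integer counts. Impaired days are capped at 125 workdays
per half-year with the inefficiency score raised to compensate, which
touches only an extreme tail.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: item-level questionnaire responses and
tariff-based utilities; correlation between cost categories beyond the
shared wage; informative (not-at-random) dropout; integer counts and
recall bias; between-window correlation in resource use. Conclusions
about the pipeline's statistical behaviour transfer; conclusions about
the clinical result do not depend on the generator at all for the
in-trial arithmetic (which is checked against the published numbers
directly) but do for replicate-level quantities, which are not
reproducible without the raw data.

## Numerical and testing choices

Fixed seeds drive every stochastic test; statistical checks use
explicit Monte-Carlo tolerances (2–3 standard errors). Problem sizes
are chosen to keep the default suite a few minutes long: parameter
recovery at n = 10,000 per arm; SUR correlation recovery at n = 5,000;
BCa coverage at the trial's own size (2 × 64) over 200 repetitions with
B = 500 bootstrap replicates, requiring ≥ 90% empirical coverage at
nominal 95%. Bootstrap seeds for scenario grids are derived
deterministically from a master seed, and identical master seeds yield
byte-identical output CSVs.

Known limitations: the SUR system is linear, so the bootstrap cloud
reflects the linear arm contrast even though the point-estimate cost
model can be a gamma GLM; the perspective-nesting identity (societal
minus public increments equal the patient/family + productivity
increment) is exact only when both equations share a regressor set
(FGLS is nonlinear in the responses otherwise, making the identity
approximate under the default covariate sets); and the linear
probability model for symptom-free status can in principle predict
outside [0, 1], which is immaterial for arm-difference estimation but
would matter for individual prediction.
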