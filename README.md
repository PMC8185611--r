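# trialcea

Trial-based cost-effectiveness and cost–utility analysis of a guided
internet-delivered cognitive behavioural therapy for insomnia (iCBT-I)
against a wait-list control, from the **societal** and the **public
health care** perspective.

The package is aimed at health-economics analysts who want the full
evaluation pipeline of a pragmatic two-arm RCT as reusable, tested code:
per-participant costing from self-reported resource use, symptom-free
status and QALY outcomes, regression-based inference with a bootstrap,
and the standard decision analytics. Because participant-level trial
data of this kind are rarely shareable, the package ships a calibrated
synthetic cohort generator so every stage can be exercised and tested
end to end.

## What it computes

For intervention (INT) vs control (CTR), the incremental
cost-effectiveness ratio

```
ICER = (Cost_INT − Cost_CTR) / (Effect_INT − Effect_CTR) = ΔC / ΔE
```

with two effect measures: symptom-free status (Insomnia Severity Index
score < 8 at 6 months) and QALYs (trapezoid area under linearly
interpolated SF-6D utilities over the 0.5-year horizon). Costs are
accumulated per participant over the follow-up from resource-use
records valued at unit prices: GP, specialist and inpatient care,
medication priced per defined daily dose with statutory/private
weighting, informal care at opportunity cost (€23.10/h), domestic help
at replacement cost (€18.33/h), travel at €0.30/km, absenteeism at the
gross daily wage (human capital approach) and presenteeism by the
Osterhaus method (impaired days × inefficiency score × daily wage),
with an HLQ (recoverable-hours) variant for sensitivity analysis.

Sampling uncertainty is handled by a nonparametric bootstrap (default
B = 2500) of a seemingly-unrelated-regression (SUR) system — a cost
equation (gamma-skewed costs, adjusted for age and baseline depressive
symptoms) and an effect equation (QALYs adjusted for baseline utility)
with correlated residuals. From the replicate cloud the package derives
bias-corrected and accelerated (BCa) confidence intervals, the ICER
with a bootstrap-acceptability interval (angular quantiles on the
cost-effectiveness plane), the quadrant distribution of the plane, and
cost-effectiveness acceptability curves over a willingness-to-pay grid.
Missing follow-up data are handled by deterministic regression
imputation with dropout-predictor correction (intention-to-treat) or by
a completers-only sample.

## Worked example

```r
library(trialcea)

cohort <- generate_cohort(cohort_params(seed = 2026))
cohort
#> Synthetic trial cohort: 128 participants (64 per arm), 2 recall window(s)
#>   follow-up completed: 116/128 (90.6%)

result <- run_scenario(cohort, scenario_config(
  perspective = "societal", outcome = "qaly", B = 2500, seed = 2026))
result
#> Economic evaluation (B = 2500 bootstrap replicates)
#>   incremental cost:       -348  (95% CI -1395 to 631)
#>   incremental effect:   0.0187  (95% CI 0.0168 to 0.0207)
#>   ICER: dominant (more effective, less costly)
#>   CE plane %: NE 25 | NW 0 | SE 75 | SW 0
```

Read: on this simulated trial the intervention saved €348 per
participant from the societal perspective while gaining 0.019 QALYs —
it *dominates* the control (cheaper and more effective), with 75% of
bootstrap replicates in the south-east quadrant. From the payer
perspective the programme fee makes it cost-increasing instead:

```r
pub <- run_scenario(cohort, scenario_config(
  perspective = "public_health_care", outcome = "qaly", B = 2500, seed = 2026))
pub
#> Economic evaluation (B = 2500 bootstrap replicates)
#>   incremental cost:        204  (95% CI 94 to 331)
#>   incremental effect:   0.0187  (95% CI 0.0168 to 0.0207)
#>   ICER: 10885  (95% CI 4591 to 17463)
#>   CE plane %: NE 100 | NW 0 | SE 0 | SW 0

pub$ceac$probability[pub$ceac$lambda == 20000]
#> [1] 0.9944
```

i.e. €10,885 per QALY gained, and a 99% probability of being
cost-effective at a willingness to pay of €20,000/QALY.

The sensitivity grid (`scenario_grid()` + `run_matrix()`) reruns the
evaluation under the HLQ presenteeism method, intervention fees scaled
by ±20% / ±50%, and a completers-only sample. A thin command-line
front end with `simulate`, `evaluate` and `sensitivity` subcommands is
in `inst/cli/trialcea.R`.

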