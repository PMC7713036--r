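# stochmsm

Counterfactual risk of a rare adverse event under **stochastic
treatment-duration regimens**, estimated by inverse-probability-weighted
discrete-time survival analysis — a target-trial emulation for
longitudinal dispensing cohorts with treatment-confounder feedback.

The motivating setting is pharmacoepidemiologic: women initiating oral
antiresorptive (bisphosphonate) therapy, followed quarterly for up to ten
years, where prolonged treatment may raise the risk of a rare adverse
outcome (atypical femur fracture) and where the factors that drive
treatment continuation — bone density, frailty — also affect the outcome
and are themselves affected by past treatment.  Standard regression
cannot adjust for such time-dependent confounding; weighting can.

## The method

Two stochastic regimens are compared on a 90-day (quarterly) grid over 40
quarters, with exposure classified per quarter from dispensing records
(proportion of days covered ≥ 0.50, with stockpiling of refills that
overlap by ≤ 30 days):

* **short_term** — discontinue treatment within 3 years, the
  discontinuation quarter uniform on quarters 1–12 (mass 1/12 each), then
  stay off; follow-up in this arm ends on any restart;
* **longer_term** — treat continuously through quarter 12, then
  discontinue in one of quarters 13–40 or never, each outcome with mass
  1/29 by default.

A woman continuously treated during the first 3 years contributes
person-time to *both* arms.  For each arm, person-quarters are weighted
by the cumulative ratio of the regimen's intervention probability of the
observed treatment value to its fitted probability (six logistic
propensity models: continuation with a cumulative-exposure term,
re-initiation, and four censoring causes), stabilized, and truncated at
50.  The saturated marginal structural model then reduces to the weighted
empirical hazard

    h_a(t) = Σ w_i(t) · event_i(t) / Σ w_i(t),
    S_a(t) = Π_{k≤t} (1 − h_a(k)),   risk_a(t) = 1 − S_a(t),

with risk differences `risk_longer(t) − risk_short(t)` and a test of the
difference in areas under the two survival curves (`Σ_t S_a(t)`, quarter
rectangle rule), all with subject-level bootstrap inference.

Because the real cohorts behind such analyses cannot be redistributed,
the package includes a synthetic-cohort generator with known
counterfactual truth (`simulate_cohort()`, `emit_dispensings()`) and a
direct-intervention Monte-Carlo oracle (`oracle_counterfactual_risk()`)
against which the estimator is validated end to end.

## A worked example

```r
library(stochmsm)
library(data.table)

cfg <- dgp_preset("default", n_subjects = 20000, seed = 1)
cohort <- simulate_cohort(cfg)
dispensings <- emit_dispensings(cohort)
panel <- build_person_quarters(
  records = dispensings,
  covariates = cohort$measurements,
  terminal = cohort$subjects[, .(subject_id, terminal_t, terminal_cause)],
  subjects = cohort$subjects)

fit <- msm_fit(panel, B = 200, seed = 2)
print(fit)
```

```
Inverse-probability-weighted stochastic-regimen fit
  short_term   risk at year 5:  616.4 per 100,000 (95% CI 347.3-852.0)
  longer_term  risk at year 5:  547.7 per 100,000 (95% CI 375.3-790.4)
  risk differences (longer - short), per 100,000:
  t    rd  ci_low ci_high
 16 -48.4  -263.2   183.3
 20 -68.8  -430.5   255.3
 40 486.0 -1409.5  2018.4
Difference in areas under counterfactual survival curves
  area short-term  : 39.72769 quarters
  area longer-term : 39.60633 quarters
  difference 0.12137 (bootstrap SE 0.07741), p = 0.1169  [B = 200]
  weights short_term   median 1.020 (IQR 0.770-1.700), 0.023% truncated
  weights longer_term  median 1.221 (IQR 1.054-1.651), 0.149% truncated
```

Reading this: each arm's counterfactual cumulative incidence is reported
per 100,000 women (the natural scale for an event this rare), the risk
differences contrast the longer-term against the short-term regimen at
years 4, 5 and 10 (quarters 16, 20, 40), and the area difference (in
quarters of event-free time over ten years) summarises the whole-curve
separation.  With ~200 events in this particular 20,000-subject synthetic
cohort the year-5 contrast is noisy (here its sign is negative, the
10-year contrast positive); the true generating contrast, available from
the oracle, is positive at both horizons:

```r
oracle_counterfactual_risk(cfg, "short_term",  n_mc = 1e5, seed = 3)$risk[40] * 1e5
# 1136.9
oracle_counterfactual_risk(cfg, "longer_term", n_mc = 1e5, seed = 4)$risk[40] * 1e5
# 1886.6
```

The stabilized weight medians sitting near 1 and the sub-0.2% truncation
fraction are the standard diagnostics that the weighting is well behaved.

`run_pipeline(pipeline_config(...))` wraps the same steps behind a YAML
configuration and writes `survival.csv`, `risk_differences.csv`,
`auc_test.json` and a run manifest; `inst/scripts/run_msm_pipeline.R` is
a command-line wrapper.

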