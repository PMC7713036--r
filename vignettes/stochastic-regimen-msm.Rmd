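---
title: "Counterfactual risk under stochastic treatment-duration regimens"
author: "stochmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual risk under stochastic treatment-duration regimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochmsm)
library(data.table)
```

## The question and the estimand

Oral antiresorptive therapy (bisphosphonates) prevents osteoporotic
fractures, but prolonged use has been linked to a rare adverse outcome,
atypical femur fracture.  The clinically relevant contrast is not "treated
versus untreated" but *duration*: what would the cumulative incidence of
the adverse event be if women discontinued therapy within three years of
starting it, versus if they continued for three or more years?

`stochmsm` estimates this contrast as a target-trial emulation with two
*stochastic* treatment regimens defined on a quarterly (90-day) grid over
ten years (40 quarters):

* **short_term** — discontinue within the first 3 years, with the
  discontinuation quarter uniform on quarters 1–12 (mass 1/12 each), then
  stay off treatment; follow-up under this arm ends if treatment is ever
  restarted.
* **longer_term** — continuous treatment through quarter 12, then either
  discontinue in one of quarters 13–40 or remain on treatment through the
  horizon, all 29 outcomes equally likely by default (the mass of the
  "never discontinue" atom is a parameter, `p_never`).

"Equal probability of discontinuation in each quarter" is read as a
uniform *marginal* law over the discontinuation quarter, not a constant
conditional hazard: uniformity of the quarters themselves is the only
reading under which every admissible quarter is equally probable.  The
implied conditional discontinuation probability given continuation so far
is `1/(13 - t)` for the short-term arm (reaching 1 at quarter 12) and
`1/(42 - t)` in quarters 13–40 for the longer-term arm.  A woman
continuously on treatment during the first three years is compatible with
*both* regimens and contributes person-time to both arms (quarter 12 on
treatment is no longer compatible with the short-term arm, whose law
forces discontinuation by then).  Incompatibility is absorbing.

The estimand for each arm is the counterfactual discrete-time risk
`1 - prod(1 - h(t))`, where `h(t)` is the population-average event hazard
among subjects still at risk had treatment followed the regimen's law.
Death is retained as a censoring process (the at-risk sets are survivors);
disenrollment and exclusion censoring are removed by weighting.

## Exposure classification

Exposure is reconstructed from dispensing records (start day, days'
supply).  Day 0 is the index date and quarter `t` is the half-open day
interval `[90(t-1), 90t)`, so no day is counted twice.  Records are
applied in order of start day: a refill that arrives while 30 or fewer
covered days remain is *stockpiled* (its supply is appended after the
prior supply ends); if more than 30 covered days remain the new
prescription takes precedence and the earlier surplus is discarded.  When
three or more prescriptions overlap the rule is applied sequentially,
pairwise, in start-day order — the most direct reading, though not the
only conceivable one.  A quarter counts as *on treatment* when its
proportion of days covered (PDC) is at least 0.50, i.e. 45 of 90 days;
the threshold is deliberately one of use rather than of full adherence,
because the outcome of interest is a harm of exposure rather than a
benefit requiring high adherence.

Covariates carry forward without expiry: the bone-density score is
updated in any quarter with a new measurement and otherwise retains its
last value; subjects with no measurement receive the cohort-mean fill
value (-2.5 on the T-score scale) plus an imputation indicator, and
`tslm` counts quarters since the last measurement.

## Weighting and estimation

Six logistic models are fit on person-quarters: treatment continuation
(given on treatment in the previous quarter; includes a main term for
cumulative exposure to date), treatment re-initiation (given off), and
one per-quarter hazard model for each stochastic censoring cause (death,
exclusion, disenrollment — in that order of precedence within a quarter).
All models adjust for the bone-density category (the four reporting
categories: above -2.0, -2.0 to -2.4, -2.5 to -2.9, at or below -3.0),
its imputation indicator, time since last measurement, frailty,
standardised age, and follow-up time; the censoring models also adjust
for current treatment.  Administrative end of follow-up at quarter 40 is
deterministic and is therefore not modelled (a configuration switch in
spirit; the cause is reported as degenerate).

The treatment weight is self-stabilized by the intervention law: at each
quarter the numerator is the regimen's probability of the *observed*
treatment value given the compatible history, and the denominator is the
fitted probability of that value.  Because both arms forbid restart, any
restart zeroes the numerator and the subject's weight from that quarter
on.  The censoring weight numerator is the pooled marginal per-quarter
probability of remaining uncensored (a saturated-in-time marginal); its
denominator is the subject's fitted conditional probability.  Censoring
factors enter through quarter `t - 1`, since a subject observed at risk
in quarter `t` has escaped censoring before it.  Fitted denominators are
floored at `1e-4` before division, and the combined weight is truncated
at 50.  On the package's default synthetic cohort the weight medians are
close to 1 (about 1.0 and 1.2 for the short- and longer-term arms) and
well under 0.5% of person-quarters are truncated.

Because the regimens are saturated in arm-time, the marginal structural
model reduces to the weighted empirical hazard
`h(t) = sum(w_i(t) e_i(t)) / sum(w_i(t))` over compatible person-quarters
— algebraically identical to a weighted logistic regression with one
indicator per arm-quarter, but exact and fast.  Survival is the product
`S(t) = prod(1 - h(k))`; risks, risk differences (longer minus short) and
the area under each survival curve (rectangle rule on the quarterly grid,
`sum S(t)`, in quarters) follow.

Inference is a subject-level nonparametric bootstrap: subjects are
resampled with replacement (equivalently, multinomial frequency weights),
and *all* models, weights and curves are recomputed in each replicate.
Percentile intervals use type-6 quantiles (`k/(B+1)`), which are slightly
wider than the default at the bootstrap sizes used here and were chosen
for their small-`B` behaviour.  The area-difference test divides the
observed difference in areas by the bootstrap standard deviation and
refers to a standard normal (two-sided).  Replicates with an empty
weighted risk set anywhere on the grid are dropped and counted; more than
20% dropped is treated as an inference failure.

Numerical notes: the logistic fits use a Newton solver with step-halving
on the binomial deviance, warm-started across bootstrap replicates; a
step of max-norm below `1e-6` (point estimates) or `0.02` (bootstrap
replicates, where resampling noise dominates far earlier) declares
convergence.  The solver agrees with `stats::glm` to ~1e-7 on the same
data (enforced by a unit test).  A model whose risk set has no events is
flagged degenerate and contributes probability 0.

## The synthetic cohort and what it emulates

Real dispensing cohorts of this kind cannot be redistributed, so the
package ships a generator whose *truth is known by construction* and uses
it for every empirical claim.  Subjects enter on treatment (the index
dispensing).  Each quarter: the latent bone-density score may be
re-measured (probability 0.10; 72% measured at baseline, the rest
mean-imputed); treatment continues or restarts according to logistic
models in the *measured* score category, frailty, age and cumulative
exposure; the rare terminal event occurs with a logistic hazard in
cumulative exposure, the *latent* score and frailty; death, exclusion
and disenrollment compete as censoring; survivors' scores drift and
respond to treatment (`+0.05` per treated quarter), closing the
treatment–confounder feedback loop.  Because treatment and censoring
depend only on measured quantities, sequential exchangeability with
respect to the observed history holds by construction, and the estimation
models are correctly specified — so estimator error isolates finite-sample
and weighting behaviour rather than model misspecification.  Dispensing
records are emitted so that day-level reclassification reproduces the
simulated exposure exactly (including stockpiled refills); this round
trip is tested.

The default configuration produces, per 20,000 subjects: roughly 180–200
events over 40 quarters (mean per-quarter hazard about 4 per 10,000,
comfortably in the rare-event regime), substantial attrition from
disenrollment and death (as in real pharmacy cohorts), declining
treatment prevalence, and strong confounding by indication: frail and
low-score women continue treatment and remain enrolled more, and restart
more after discontinuing.  The event scale sits above the handful of
events a directly scaled-down real cohort would show; with only a few
dozen events the unweighted estimator's own sampling noise would swamp
any bias margin one could certify, so the scale was set where the
bias-versus-truth separation is a stable property rather than a seed
lottery.  Preset variants (`dgp_preset()`) provide a *null* process
(hazard independent of treatment and of the treatment-responsive score;
both arms share the same truth), a *strong* cumulative effect (0.22 per
quarter on the log-odds with a higher event rate), and a *reduced*-scale
variant with an elevated event rate for 2,000-subject studies.

What the generator does **not** emulate: staggered calendar entry,
multi-drug switching and dose, measurement error in dispensing data,
unmeasured confounding, and the extremely sparse event counts of the real
phenomenon (tens of events per ~90,000 women).  Passing tests therefore
demonstrate that the estimator recovers the truth *when its assumptions
hold at tractable scale*; they cannot certify behaviour under violations
the generator does not produce.

## The ground-truth oracle

`oracle_counterfactual_risk()` computes each arm's true risk by direct
intervention: treatment is drawn from the regimen's conditional
discontinuation law instead of the observational model, disenrollment and
exclusion are switched off (the estimand removes them by weighting),
death is retained, and the discrete-time at-risk-averaged hazard product
is evaluated by Monte Carlo (with a Greenwood standard error).  On a
degenerate configuration (no noise, homogeneous baseline, no death) the
oracle is validated against an exact closed-form enumeration of the
discontinuation-time paths.

## Design choices where the design was open

* *Initiation versus continuation models.*  Everyone enters on treatment,
  so quarter-1 exposure is governed by the continuation model (cumulative
  exposure zero) and the "initiation" model describes off-to-on
  re-initiation.  Its complement (staying off) is exactly the denominator
  the short-term arm needs after discontinuation, so re-initiation
  probabilities do enter the weights even though restarts themselves
  carry numerator zero.
* *The "never discontinue" atom.*  The longer-term arm's law needs a mass
  for remaining on treatment through the horizon; equal weight with each
  discontinuation quarter (1/29) is the symmetric default and is
  configurable.
* *Quarter 12 under the short-term arm.*  "Discontinuation within three
  years" is read as off-treatment from some quarter `d <= 12`, so being on
  treatment in quarter 12 is incompatible with the arm (conditional
  discontinuation probability 1 at quarter 12).
* *Stabilization numerators.*  The treatment component is self-stabilized
  by the intervention law; the censoring component uses pooled marginal
  per-quarter uncensored probabilities.  These choices make the weights
  center near 1, as weight diagnostics on the default cohort confirm.
* *Confidence intervals* are pointwise subject-level bootstrap percentile
  intervals; the area test uses a bootstrap-Wald normal approximation.
  Both are assumption-light and are validated by simulation (coverage and
  type-I error studies in the test suite) rather than asserted.

## Known limitations

* At early horizons the *unweighted* short-term-arm estimate is nearly
  unbiased by construction: its early risk sets share the on-treatment
  person-time with the longer-term arm (dual-arm contribution), so
  selective-discontinuation bias (downward) and exposure-accumulation
  bias (upward) largely offset there.  The "weighting matters"
  demonstration is therefore anchored at the 10-year horizon for both
  arms (where both margins are large and stable) and additionally at
  years 4–5 for the longer-term arm.
* Strong confounding strains positivity: regimen histories that are very
  rare under the observational law (e.g. a frail, low-score woman forced
  to discontinue at quarter 12) produce weights near or above the
  truncation bound, and truncation then trades variance against a small
  systematic underestimate.  The default generator was deliberately kept
  below the strength at which this bias becomes visible relative to
  bootstrap uncertainty.
* Percentile intervals at `B = 100` with a few dozen events undercover
  mildly; the coverage study in the test suite quantifies this at the
  reduced scale.
* No competing-risk (subdistribution) estimand is offered; death is
  censoring, matching the follow-up rules being emulated.

## Problem sizes used by the validation suite

The suite exercises: exposure classification against a brute-force
day-level oracle (500 random dispensing configurations); exhaustive
enumeration on a hand-written 12-subject fixture; a 20,000-subject
no-confounding equivalence check; the headline parameter-recovery study
at 20,000 subjects with a 200-replicate bootstrap against a
100,000-subject Monte-Carlo oracle; type-I-error calibration of the area
test over 200 null cohorts of 2,000 subjects (100 bootstrap replicates
each) with a 40-cohort power companion under the strong preset; and a
50-repetition coverage study at 2,000 subjects.  These sizes are the
package's chosen balance between Monte-Carlo resolution and a test suite
that runs in tens of minutes on one core.

## A worked example

```{r example, eval = FALSE}
library(stochmsm)

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

truth <- oracle_counterfactual_risk(cfg, "longer_term",
                                    n_mc = 100000, seed = 101)
truth$risk[40]   # the estimand msm_fit targets for the longer-term arm
```

`run_pipeline()` wraps the same steps behind a serializable
configuration, writes `survival.csv`, `risk_differences.csv`,
`auc_test.json` and a run manifest whose per-quarter compatible-subject
counts mirror the attrition flow of a duration-regimen cohort, and is
byte-reproducible under a fixed configuration.
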