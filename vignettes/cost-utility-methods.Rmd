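---
title: "Methods: within-trial cost-utility analysis and lifetime SPPB modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-utility analysis and lifetime SPPB modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sppbcea)
```

## The problem

`sppbcea` implements the health-economic evaluation of a 12-month
community-based group exercise and behaviour-maintenance programme for
older adults (65+) at risk of mobility limitation, identified by a Short
Physical Performance Battery (SPPB) score of 4–9 at entry. The evaluation
has three parts:

1. **Micro-costing** of programme delivery (session leader time, venue
   hire, coordination, equipment, training), producing a cost per group and
   per participant.
2. **A within-trial cost-utility analysis** over 24 months: EQ-5D-5L
   responses valued through a crosswalk tariff, QALYs by the
   area-under-the-curve method, NHS/Personal Social Services resource-use
   costs from 6-month recall questionnaires, multiple imputation of missing
   data, covariate-adjusted incremental costs and QALYs, and a bootstrap
   cost-effectiveness acceptability curve (CEAC).
3. **Lifetime extrapolation** with a 14-state annual-cycle Markov cohort
   model (SPPB 0–12 plus death), with probabilistic and one-way
   deterministic sensitivity analysis.

## Costing model

Each resource line is a `cost_component` with a basis: `per_session`
(scales with the 64 sessions), `per_participant` (scales with the average
group size of 15.2), `per_group` (fixed), or `per_programme_share` (fixed
cost split across `share_divisor` programmes — e.g. one trainer serving
four trainees who each deliver four programmes gives a divisor of 16).
Capital items are costed at their *equivalent annual cost*,
`capital / annuity factor`, with the in-arrears factor
$(1-(1+r)^{-n})/r$ and the in-advance factor $(1+r)$ times that. **Annuity
timing defaults to payments in advance**, which reproduces the reference
figure of £29.16 for £136.27 of equipment over 5 years at 3.5% (in arrears
gives £30.18); both are available. Money is carried at full double
precision and only rounded — half-up — at presentation
(`round_money()`). A "1.5 day" duration converts at 7 working hours per
day, consistent with 10.5 h of trainer time. Session count and group size
are arguments, never constants.

The shipped costing specification treats *row-level* table cells as ground
truth. The published per-participant cells imply an effective group size
of ≈15.22 rather than the stated 15.2, and the printed grand total exceeds
the sum of the available rows, so totals are defined as the sum of rows;
the per-group cells that do not involve group size reproduce to the penny.
The refreshments row is encoded as 9.708125 items per session — the
attendance-weighted figure implied by its printed cell — rather than the
nominal "one per participant per session".

## Utilities and QALYs

Value sets are consumed as lookup tables (`value_set`), never re-derived:
tariff construction and the SF-36 → SF-6D scoring algorithm are out of
scope. The toy tariffs generated by `generate_value_set()` are monotone in
every dimension, anchor full health at 1, and hit the documented floors
(−0.594 for the EQ-5D-3L crosswalk, −0.285 for EQ-5D-5L native, 0.203 for
SF-6D). Per-level decrements are convex (exponent 1.35), mirroring the
shape of published tariffs and giving a fine utility grid near full
health.

QALYs use trapezoidal areas over months 0–6, 6–12 and 12–24. Discounting
is discrete annual at 3.5%: year 1 undiscounted, and the entire
12–24-month trapezoid discounted by $1/1.035$ as one block. The source
analysis says only that costs and QALYs "beyond 12 months" were
discounted; whether the second year was discounted as a block or
month-by-month is not stated. The block convention was adopted for
transparency (it makes `qaly_auc(1,1,1,1)` exactly $1 + 1/1.035$) and is
applied identically to costs, so the two streams share one time axis.
Missing utilities are an *error* in `qaly_auc()`: imputation is a separate,
explicit step.

## Resource-use costing

Period costs are dot products of recall counts with a unit-cost table; an
unpriced item raises an error rather than contributing a silent zero.
Months 12–18 were never observed (no questionnaire at 18 months), so that
period's cost is the arithmetic mean of the 6–12 and 18–24-month costs,
computed *after* multiple imputation so the rule stays deterministic given
completed data. The intervention delivery cost (£622 per participant by
default) is attributed wholly to year 1 and not discounted; control-arm
education workshops are costed at £0 by default. Baseline resource use
enters the analysis only as an adjustment covariate, not in the 24-month
totals.

## Missing data

Missing utilities and period costs are multiply imputed by predictive mean
matching (PMM) within chained equations (`pmm_impute()`), with m = 50
imputations by default. Donor pool size (5), sweeps (10) and the predictor
set (arm, age, sex, site, attendance, plus the current values of the other
incomplete variables) are conventional defaults declared here because the
source analysis does not state them; all are arguments. Imputation
operates on period costs and timepoint utilities, not on individual
resource items, keeping the imputation model tractable. Each imputed value
is the observed value of a matched donor, so imputations never leave the
observed support. A master seed spawns one substream per imputation.
Downstream estimates are pooled by Rubin's rules with Barnard–Rubin
degrees of freedom when a finite complete-data df is supplied.

## Within-trial incremental analysis

Generalised linear models regress per-participant QALYs and total costs on
arm plus baseline covariates (age, sex, site, baseline utility, baseline
cost by default). The base-case family is gaussian/identity for both
outcomes — the source states only "generalised linear models" — with
gamma/log available for costs, in which case the arm contrast is the
average marginal effect with a delta-method variance. Incremental pairs
are classified as dominant (cheaper, more effective), dominated, or an
ICER reported raw and rounded to a granularity (£50 default; £1000 for
headline complete-case figures). Bootstrap uncertainty uses case
resampling stratified by arm, re-running the adjusted model per replicate;
with multiple imputation, bootstrapping happens within each imputation and
the draw clouds are pooled. The ICER's percentile interval is read off the
net-benefit scale (the thresholds where the CEAC crosses 2.5% and 97.5%),
which stays well defined when draws span quadrants.

## Lifetime Markov model

Fourteen states: SPPB 0–12 plus absorbing death; annual cycles; cohort
entry at trial month 24. Transition dynamics are a proportional-odds
ordinal regression of next-year SPPB on current SPPB, age and sex, fitted
to *control-arm* data only — as are the state cost and utility lines — so
any intervention effect flows exclusively through the two arms' SPPB
distributions at entry. Mortality comes from a life table, applied
identically to every living state: the no-mortality-effect assumption is
structural, and both arms' life expectancies agree to 1e-9 by
construction. The ordinal form is a design choice (the source says only "a
statistical model"); the prediction interface is pluggable.

Numerical conventions: cycle rewards accrue to start-of-cycle occupancy
with no half-cycle correction in the base case (an optional flag enables
it); cycle 0 is discounted by $(1+r)^{-2}$ so the model phase continues the
trial's discount clock; ages between the 65–95-by-5 grid map to the
nearest grid profile (77 → 75); the horizon caps at age 100; start
distributions are empirical 24-month SPPB histograms per arm. The
published model-phase results are **not** reproduction targets: the
parameter appendix underlying them is unavailable, so all model parameters
here are synthetic stand-ins and the model is validated by structural
properties (row stochasticity, conservation, symmetry, mortality
neutrality, matrix-power oracles) instead.

## Sensitivity analysis

PSA samples parameter distributions (beta for utilities, gamma/lognormal
for costs, dirichlet for probability vectors, normal, fixed), re-runs the
full lifetime model per draw (default n = 5000), and reports percentile
credible intervals and a model-based CEAC. Draws producing invalid inputs
(utility above 1, negative cost, death probability outside [0,1], invalid
start vector) are rejected and counted — never clamped — to avoid silent
distortion. One-way analysis re-evaluates the deterministic model at each
parameter's bounds and ranks by the swing in net monetary benefit at
£20,000/QALY.

## The synthetic-data generator

`generate_trial()` emits the *stated world*: 777 participants, 1:1
allocation, 66% female, age ~ N(77, 6) truncated at 65, three sites,
baseline SPPB 4–9, a 24-month SPPB contrast of 0.49, true incremental
QALYs of 0.040 and incremental total cost of −£103 (including the £622
delivery cost), and 58% complete cases. Mechanics worth knowing:

* Utilities are generated on a latent scale and snapped to the nearest
  value-set profile, so generation and lookup are mutually consistent. The
  post-baseline utility lift is `0.040 / (0.75 + 1/1.035)` per timepoint —
  the discounted AUC weight of a constant lift — so the configured QALY
  effect is embedded on the discounted scale. The hard ceiling at utility
  1 attenuates the realised effect by ≈0.001–0.002; this is inherent to
  bounded utilities (real trials face the same ceiling) and is well inside
  the pipeline's recovery tolerance.
* Resource counts are negative binomial with means that fall
  exponentially in current SPPB (so the state-cost regression has true
  structure to recover) and a direct intervention multiplier computed at
  generation time so the *expected* discounted resource-cost difference,
  plus the delivery cost, equals the configured incremental cost.
* Missingness is monotone (a missed booklet implies all later booklets
  missed) and MAR: the number of complete cases is exactly
  `round(0.58 × n)` = 451, selected by a logistic score of arm, attendance
  and baseline utility — all fully observed.
* `truth` records both the configured effects and the realised
  complete-data contrasts, plus per-participant true QALYs and costs.

What the generator does **not** emulate: site-level clustering, the
baseline cost imbalance seen in the real data (a knob exists, off by
default), recall bias, and item-level missingness patterns. A green
recovery test therefore establishes that the pipeline is internally
consistent and unbiased under MAR with these marginals — not that it would
reproduce any particular real dataset.

## Known limitations

* The SF-6D sensitivity analysis and the published model-phase numbers are
  not reproduction targets (inputs unavailable); only structural properties
  of the model are asserted.
* PMM defaults (donors, sweeps, predictors) are declared conventions, not
  inferred from the source analysis.
* The bootstrap-within-imputation ordering for combining MI with
  bootstrap is one of several defensible choices; it was chosen so each
  draw conditions on a single completed dataset.
* Acceptance-scale simulations in the test suite run the 50-seed
  replication with m = 10 imputations and 5 sweeps (rather than 50/10) to
  stay inside the runtime budget; the number of imputations affects only
  the variance of the pooled estimate, not its expectation, so the bias
  check is unaffected.
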