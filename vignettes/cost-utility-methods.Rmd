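---
title: "Methods: trial-based cost-utility analysis and the ten-year Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis and the ten-year Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urocea)
```

## The decision problem

Recurrent bulbar urethral stricture can be treated by endoscopic urethrotomy
(minimally invasive, cheap, but with a high chance of further recurrence) or
by open urethroplasty (more invasive and costly, with better prospects of
long-term cure). `urocea` implements the economic-evaluation machinery for a
two-arm randomised comparison of the two procedures: patient-level
micro-costing, EQ-5D-5L-based QALYs over 24 months, a within-trial
cost-utility analysis, and a ten-year three-state Markov model. Because the
underlying trial data are not publicly available, the package ships a
synthetic data generator that reproduces the *structure* of such a trial and
records its own ground truth, so every estimator can be tested for parameter
recovery.

## Micro-costing

Each operation is costed bottom-up: theatre minutes, surgeon, anaesthetist
and nurse time, consumable packs, bed-days and catheter days, each multiplied
by a unit cost taken from an external table (`unit_costs.csv`). Unit costs
carry a price year and are converted to the 2017 price year by the ratio of
consumer price index values, `amount * cpi[target] / cpi[from]` — an
operation that is the identity within a year and transitive across years.
Re-interventions during follow-up are costed by exactly the same process as
the index procedure. Follow-up primary/secondary-care contacts and
out-of-pocket items enter as additional rows, giving three nested
perspectives per patient:

* *intervention*: index procedure plus re-interventions;
* *NHS*: plus follow-up service use;
* *societal*: plus patients' out-of-pocket costs.

Costs attach to recall periods, not calendar dates, so they are never
rescaled across follow-up. Whether second-year costs should be discounted in
a two-year within-trial analysis is a judgement call; we discount components
falling after day 365.25 at 3.5% a year in the default within-trial analysis
and expose `discount_rate = 0` as the off-switch in `cost_patients()`.

## QALYs

EQ-5D-5L profiles are scored by a pluggable tariff. Licensed national value
sets are not embedded; `toy_tariff()` is a transparent synthetic value set
(each level above 1 subtracts 0.05 per dimension) whose 0.05 utility grid
also makes degenerate generator configurations exactly recoverable. QALYs are
the area under the utility-time curve (trapezoid rule over day offsets,
divided by 365.25), anchored at the first observation: randomisation/baseline
for the base case, the pre-surgery assessment for the post-surgery analyses.
Observations beyond 760 days from the anchor are truncated to day 760, which
bounds the integration window.

Two further transforms mirror the trial's sensitivity analyses. *Rescaling*
multiplies the observed-span QALY by `730 / observed span` to put arms with
different waiting times on the nominal two-year footing — a pure
multiplication, asserted as such in tests. *Discounting* splits the series at
year boundaries and weights each sub-segment by `(1 + r)^-k` for the year `k`
containing its midpoint; with constant full health over exactly two years
this gives `1 + 1/1.035`.

Complete-case inclusion follows three rule sets: participants without an
index operation need baseline, 18-month and 24-month post-randomisation data;
operated participants need the window's two endpoint assessments plus at
least one mid-range point (3/6/9/12 months post surgery or 18 months post
randomisation, the 24-month post-randomisation point also counting for the
post-surgery window). The within-trial analysis additionally requires
complete cost data — the natural reading of the trial's smaller analysed
base-case sample.

## Within-trial cost-utility analysis

Incremental cost and QALY (urethroplasty minus urethrotomy, a fixed
direction) come from a two-equation seemingly unrelated regression of cost
and QALY on identical regressors: allocated arm, the dichotomised
time-since-last-procedure stratum, and baseline utility. With identical
regressors the coefficient estimates equal per-equation least squares
(Kruskal's equivalence) — asserted against an independent `lm()` oracle in
every test run — while the joint residual covariance supplies the correlation
between the two increments. Adjusted arm means are evaluated at the grand
covariate means, so they differ by exactly the arm coefficient.

The increment pair is classified as dominated (dearer, fewer QALYs),
dominant (cheaper, more QALYs) or an ICER `Δc/Δe`; a zero QALY increment with
non-zero cost increment is resolved by cost minimisation and flagged.
Uncertainty uses a non-parametric bootstrap stratified by arm (resampling
within arm preserves arm sizes and makes empty-arm resamples impossible),
B = 1000 by default with percentile intervals — the trial report states
neither B nor the interval method, so these are package defaults. The CEAC
reports, per willingness-to-pay threshold, the fraction of draws in which
each strategy has the highest net monetary benefit `λE − C`; ties go to the
comparator, so at `λ = 0` the intervention's probability is exactly the
fraction of draws in which it is cheaper, and two-strategy probabilities sum
to one.

Missing utilities are multiply imputed at the timepoint level by chained
equations with predictive mean matching (predictors: arm, stratum, baseline
utility, adjacent timepoints, total observed cost; parameters drawn from
their posterior before donor matching with k = 5 donors). QALYs are
recomputed on each of m = 25 (default) completed datasets and increments
pooled by Rubin's rules; the trial report does not state m. With no missing
data the pooled result reproduces the complete-case result exactly. CEACs
under imputation stack roughly `B/m` bootstrap draws per completed dataset.

## The ten-year Markov model

Three states: symptom-free, symptomatic, deceased (absorbing). Cycles are six
months by default, matching the trial's follow-up rhythm (the cycle length is
configurable; the trial report does not state one). The cohort starts 100%
symptom-free after the initial procedure, whose cost is incurred at time
zero. Per cycle, a flat background death probability is applied first and
recurrence among survivors second — multiplicative competing risks, so rows
of every transition matrix sum to one without renormalisation, and inputs are
validated rather than silently renormalised. Recurrence probability depends
on the *last procedure received*; internally the engine therefore expands
occupancy by last procedure while reporting the three-state trace.
Symptomatic survivors are re-intervened within the cycle and return to
symptom-free; the re-intervention procedure follows the recurrence policy
(`observed_mix` with a switch probability, `always_same`, `always_other` —
the two policy scenarios of the reported sensitivity analyses). States are
never absorbing cures: repeat recurrences can cycle indefinitely, an
assumption the available description does not pin down.

Rewards (state utilities × cycle length, follow-up costs, re-intervention
costs) accrue at cycle-start times and are discounted at 3.5% a year for both
costs and QALYs; with annual cycles, full health and no transitions this
yields `Σ 1.035^-t = 8.6077` over a decade. No half-cycle correction is
applied by default (an optional flag averages start/end occupancy and
discounts at cycle midpoints). A transient per-recurrence utility decrement
exists as a parameter but defaults to zero, matching the base structure in
which quality-of-life loss during recovery from re-interventions is not
modelled. The engine is validated against an independent individual-level
micro-simulation oracle (10^5 trajectories) in the test suite.

The shipped `markov_params.yaml` is an **illustrative, non-canonical**
parameter set: the canonical supplementary parameter table is not available.
Initial procedure costs are fixed at the within-trial
intervention-plus-re-intervention arm means (4332/2209); the recurrence,
utility and follow-up-cost parameters were calibrated once so the engine
lands in the regime the published estimates imply — ten-year discounted costs
near £8.0k/£6.6k, both strategies' QALYs rounding to 7.6, and an ICER well
above £100,000 per QALY. Probabilistic sensitivity analysis assigns beta
distributions to probabilities and utilities and gamma to costs, matched by
method of moments from mean and standard error (default: 20% relative
standard error, a package choice in the absence of reported SEs); infeasible
beta moments raise an error naming the parameter.

## The synthetic trial generator

`sim_config()` defaults describe the study conditions: 110 participants per
arm, 1:1 allocation with a binary stratum, 5% crossover, 3% never operated,
per-procedure gamma resource-use distributions (length-of-stay means/SDs are
the published 1.34 (0.95) and 0.52 (1.0) days), longer waits before
urethroplasty (90 vs 40 days), a geometric monthly re-intervention hazard
over months 1–24 post surgery (0.4%/1.2% per month) with 50% switching, and
EQ-5D-5L at the eleven scheduled collection points with missingness rising
from 10% to 45% over follow-up. Missingness is missing-at-random via a
logistic link on arm and centred baseline utility — the empirical mechanism
is unknown, so MAR is an explicit assumption; it is what makes imputation
demonstrably different from complete-case analysis. Latent utilities map to
profiles on the toy tariff's 0.05 grid by randomised rounding, making scored
utilities unbiased for the latent means and degenerate configurations exact.

Observation days are capped at 760 from randomisation. A consequence worth
knowing: post-surgery windows on synthetic data span *less* than 730 days, so
rescaling can move QALYs in either direction, whereas the trial's post-surgery
spans exceeded it. The generator also does not model recruitment-site
clustering, the minimisation algorithm, seasonal effects, or missingness in
cost data. Passing tests therefore demonstrate correctness of the estimator
chain under a known MAR, constant-hazard, flat-trajectory world — not that
the trial's own substantive results would be recovered from real data.

Every simulation records a `TruthRecord`: per-arm expected costs, QALYs and
the analytic 24-month recurrence probability, computed by re-simulating the
same configuration at large n (default 10,000/arm) without missingness. The
truth record deliberately reuses the costing and scoring code — it captures
the generator's expectations for estimator-recovery tests, while the AUC,
costing and Markov arithmetic have their own independent hand-computed and
micro-simulation oracles.

## Numerical and testing choices

* 365.25 days per year; nominal window 730 days; cap 760 days.
* Whole-percent table cells round half up (0.994 → 99).
* All randomness flows from one root seed, split per stage, so each pipeline
  stage is independently reproducible and reruns are byte-identical.
* Singular regression designs error naming the collinear columns; in fully
  degenerate (no-noise) configurations the constant baseline-utility
  covariate is therefore dropped from the adjustment set by the caller.
* Test problem sizes are the package's own accuracy/runtime trade-off:
  bootstrap-coverage checks use 200 replicates of 200/arm with B = 400;
  the imputation-versus-complete-case comparison uses 100 replicates at
  trial scale with m = 10; parameter recovery uses 5000/arm; the Markov
  micro-simulation oracle uses 10^5 trajectories.

## Limitations

The tariff shipped for tests is synthetic; substantive utilities require a
licensed national value set supplied as a file. Mortality is a flat
background rate with no age dependence. The Markov default parameters are
calibrated illustrations, not estimates. The CEAC machinery is written
generically over draws but exercised only for the two-strategy comparison,
and no value-of-information quantities are computed.
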