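---
title: "Multistate life table health expectancies from panel disability data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate life table health expectancies from panel disability data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

healthexpect estimates how much of remaining adult life is lived with
functional limitation, from longitudinal survey panels of the kind collected
in rural low-income settings: a few biennial waves, disability measured by
SF-12-style limitation items, mortality ascertained between waves, and
subjects clustered in villages. This vignette is the package's account of
the model, its assumptions, the numerical choices, and what the synthetic
test bed does and does not establish.

```{r setup}
library(healthexpect)
```

## Disability states and coding

Respondents are classified at each wave into four states from two items on
health-related limitation in moderate activities (cooking, walking to
meetings, tending livestock) and strenuous activities (carrying loads, farm
work, pounding maize):

* **healthy** — "not limited" on both items;
* **moderate** — "limited a little" on at least one item, "limited a lot"
  on neither;
* **severe** — "limited a lot" on either item, or assessed by the
  interviewer as too ill or weak to respond at all;
* **dead** — absorbing; between-wave deaths are ascertained by the survey
  team even for non-respondents.

`code_state_3level()` implements this mapping; it is total on substantive
responses and order-monotone (worsening an item never improves the coded
state). A respondent with one item missing and no qualifying answer on the
other is coded missing rather than healthy, because a limitation cannot be
ruled out. Two alternative codings support robustness analyses: a two-level
healthy/limited collapse (`code_state_2level()`) and a pain-based coding
(`code_state_pain()`). For the pain item only a binary cut ("moderately" or
worse counts as limited) is conventional; to retain a three-state pipeline
we split the limited side as {moderately, quite a bit} → moderate and
{extremely} → severe, keeping the conventional cut intact. The mapping is
an argument, not a constant.

## From waves to person-periods: the midpoint convention

Exact dates of deaths and state changes are unknown, so each event is
assigned to the midpoint of its observation interval. `build_person_periods()`
realises this as: exactly one transition per interval, placed after the
first year. A 2-year interval from state *A* at age *a* to living state *B*
yields the annual records (*a*, *A*→*B*) and (*a*+1, *B*→*B*); a death
yields the single record (*a*, *A*→dead). For a skipped wave (a 4-year
interval) the transition is placed at the integer year nearest the interval
midpoint, with stayer years before and after; `drop_long = TRUE` instead
drops intervals longer than `max_gap`. How longer gaps were handled in the
motivating studies is not documented anywhere we know of; the
nearest-midpoint placement is our documented choice.

The analysis sample keeps subjects aged 45+ at first interview who were
interviewed at least twice or were interviewed once and died between waves;
records with missing sex, age or coded state are dropped first
(`apply_sample_filters()` reports all removal counts).

## The discrete-time hazard model

Annual transitions are modelled per origin state *i* as a multinomial logit
over destinations *j*, baseline "remain in *i*":

$$
\eta_{ij}(a, m) = \beta_{0ij} + \beta_{1ij}(a - c) + \beta_{2ij}(a - c)^2
  + \beta_{3ij} m,
\qquad
p_{ij} = \frac{e^{\eta_{ij}}}{1 + \sum_{j'} e^{\eta_{ij'}}},
$$

with *a* age, *m* a male indicator and *c* = 65 a centering constant that
stabilises the quadratic term numerically. The printed form of such models
is often a per-pair binary logit; a joint per-origin multinomial logit is
the only way to satisfy row-stochasticity exactly without post-hoc
renormalisation, so it is the default, and a binary-logit-with-
renormalisation mode (`mode = "binary"`) is kept for sensitivity. Point
estimates ignore the village clustering; clustering enters through the
bootstrap, which is where all the uncertainty statements come from.

`fit_transition_model()` maximises the likelihood by Newton–Raphson with
analytic gradient and Hessian on a column-scaled design. Numerical policy:

* destinations never observed from an origin are **structural zeros**
  (probability identically 0), not divergent estimates;
* quasi-separated destinations (the unpenalised fit diverges or a scaled
  coefficient passes 15) are refitted with a ridge penalty of $10^{-6}$ and
  flagged in the convergence diagnostics;
* convergence requires the maximum score component below $10^{-10} n$, so
  averaged fitted probabilities reproduce observed destination frequencies
  per origin to well below $10^{-8}$;
* fitted probabilities are evaluated only on ages 45–90; outside that range
  the quadratic predictor is unsupported and can turn over, so evaluation
  clamps to the boundary rather than extrapolating. The cap is an argument.

The suite cross-checks the fitter against `nnet::multinom` and against
closed-form cases (intercept-only fits equal empirical proportions; all-zero
coefficients give probability 1/4 to each of four outcomes).

## Health expectancies: microsimulation and its exact oracle

`run_microsim()` ages a synthetic cohort (default 100,000, starting ages
45/55/65/75) forward one year at a time: each member draws a destination
from the fitted annual probabilities at their current age and sex.
Person-year crediting is never stated explicitly in the life-table
literature we emulate, so the package fixes a **mid-cycle convention**
consistent with the midpoint philosophy: stayers credit a full year to
their state; living movers credit half a year to origin and half to
destination; deaths credit half a year to the origin state. A
"start-state-full-year" variant sits behind `credit = "fullyear"` for
sensitivity. Survivors in the year before the age cap (default 110)
receive a terminal half-year credit and die; with clamped probabilities
annual mortality is bounded away from zero, so the truncated tail is
negligible.

`analytic_expectancies()` propagates the expected occupancy vector through
the same age-specific matrices with identical crediting — the exact
expectation of every microsimulation cell, with no Monte-Carlo error. It is
the package's central oracle: the suite requires microsimulation cells to
sit within four Monte-Carlo standard errors of the analytic values for
random transition schedules, and both engines to reproduce closed-form
limits (certain death ⇒ total LE exactly 0.5 y; constant annual death
probability *q* ⇒ LE equal to a finite geometric sum, ≈ (1−q)/q + 0.5).
Sex-specific expectancies are computed within sex strata of one mixed
cohort, not from separate runs. `conditional_expectancies()` starts the
whole cohort in one state (sex mix unchanged); the joint-weighted mixture
of the per-sex conditional rows reproduces the unconditional table to
1e−9, which the suite asserts.

Initial cohort distributions are supplied by the caller;
`empirical_initial_distribution()` takes the sex-by-state distribution of
respondents within ±2 years of the starting age, which is what the
end-to-end pipeline uses.

## Bootstrap confidence intervals

`bootstrap_he()` re-runs the entire pipeline — resample, refilter, rebuild
person-periods, refit, re-simulate — on stratified resamples and takes
central percentile intervals (default 95%, 499 replicates). The resampling
unit is the subject with all their waves, drawn with replacement within
village strata, preserving each village's subject count; a village-as-PSU
mode (`unit = "village"`) is provided because survey-design language about
"stratification by village" is genuinely ambiguous between the two. The
percentile rule is stated bit-exactly: with *R* sorted replicate values the
*q*-quantile sits at position 1 + *q*(*R* − 1), linearly interpolated
(replicates 1…499 give a central-95% interval of [13.45, 486.55]).
Replicate refits that fail are dropped and counted; more than 10% failures
escalates to an error. Replicate *r* derives all its randomness from
`base_seed + r`, so CI tables are exactly reproducible.

## The synthetic panel generator

`panel_spec()` + `simulate_panel()` generate the test bed: latent annual
health histories as a first-order Markov chain under a known transition
schedule, observed through a three-wave biennial survey instrument. The
defaults emulate a rural mature-adult panel: 2,000 subjects aged 45+
(exponentially declining age distribution), 47% male, clustered in 121
villages over 3 regions, waves in 2006/2008/2010, initial disability
prevalence by age band (72/22/5% at 45–64, 54/32/14% at 65+), per-wave
response declining with age and limitation, and death always ascertained.
The default true schedule was calibrated, once, to published anchor
quantities for this population: a healthy 45-year-old man has under 0.08
probability of leaving healthy within a year; severe-state mortality at 45
is about six times healthy mortality; recovery from moderate limitation is
common at 45 (≈0.37/yr) but falls below progression-plus-death around age
70 for women; full recovery from severe limitation is nearly gone by 75.
Limitation items are realised so the three-level coding inverts the latent
state exactly, which the suite asserts wave by wave; auxiliary items (work
for income, pain interference, life satisfaction) are drawn independently
across waves given state — sufficient for cross-tab descriptives, not for
studying serial correlation in those items.

What the generator deliberately does **not** emulate: calendar-time trends
in disability prevalence (the life-table method itself assumes stationary
rates), HIV-status heterogeneity, region-specific cultural differences, and
any dependence of item errors on the latent state (coding is exactly
invertible, so coding error contributes nothing to the synthetic results).
Passing tests therefore demonstrate the estimation machinery, not
robustness to measurement error.

## Known limitation: the midpoint approximation under rapid turnover

With truly annual dynamics observed every two years, the midpoint
decomposition miscounts multi-transition paths (a round trip
healthy→moderate→healthy is recorded as two stayer years). The estimator
is therefore mildly inconsistent for the annual coefficients; its bias does
not shrink with sample size while standard errors do, so at large n fitted
coefficients can sit several standard errors from the generating values
even though combined-cohort life expectancy is recovered to within a few
percent. The package surfaces this honestly in its end-to-end suite rather
than hiding it: it is a property of the method (shared with the studies the
package emulates, which acknowledge that single-transition intervals
"likely miss shorter term transitions"), not of the implementation.
Interval-likelihood (matrix-product) estimation would remove the bias but
is out of scope here. The first-order Markov assumption (no
state-duration dependence) is likewise inherited from the method.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale testing conditions: oracle
equivalence uses five random schedules at cohort size 100,000;
closed-form limits use 100,000; end-to-end recovery uses panels of 5,000
subjects over three seeds; bootstrap coverage uses 200 synthetic panels of
800 subjects with 99 replicates each, checking that nominal-95% intervals
for total life expectancy at 45 cover the generating value between 90% and
99% of the time.

## A minimal run

```{r, eval = FALSE}
spec <- panel_spec(n_subjects = 1000, seed = 7)
panel <- simulate_panel(spec)
records <- code_records(panel$records)
periods <- build_person_periods(apply_sample_filters(records))
fit <- fit_transition_model(periods)

init <- empirical_initial_distribution(records, 65)
cohort <- cohort_spec(65, size = 100000, initial_distribution = init,
                      seed = 1)
health_expectancies(run_microsim(fit$params, cohort))
```
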