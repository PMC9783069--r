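---
title: "Age-stage, two-sex life tables: models, conventions and design"
author: "twosexlt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage, two-sex life tables: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twosexlt)
```

## The model

A synchronized cohort of eggs laid on one day is followed at a daily
census until the last individual dies. Each individual traverses an
ordered stage ontology — by default egg, six larval instars, prepupa,
pupa, then one of two parallel terminal stages, female or male — at its
own pace. Age `x` counts days since oviposition, starting at 0.

All quantities are plain cohort fractions and means, which is what makes
the framework robust: `s_xj` is the fraction of the initial `n` eggs
observed alive at age `x` in stage `j`; summing over stages gives the
age-specific survival `l_x` (so `l_0 = 1` and `l_x` never increases, up
to floating-point noise in the stage sum). The age-stage fecundity
`f_xj` is the mean egg count per female alive at that age, nonzero only
in the female stage, and the age-specific fecundity is the
occupancy-weighted mean

$$m_x = \frac{\sum_j s_{xj} f_{xj}}{\sum_j s_{xj}},$$

defined as 0 at ages where no one is alive. Net maternity is
`l_x m_x`, and the net reproductive rate is its sum,
$R_0 = \sum_x l_x m_x$, which equals total eggs laid divided by `n`
exactly — a useful invariant that the tests assert to machine precision.

The intrinsic rate of increase `r` solves the discrete Euler–Lotka
equation

$$\sum_{x \ge 0} e^{-r(x+1)}\, l_x m_x = 1,$$

with the one-day shift in the exponent: eggs laid by a mother of age `x`
enter the population at age 0 on the next census day. The left-hand side
is strictly decreasing in `r`, so the solver is a bisection from an
expanding initial bracket `[-5, 5]` down to a residual tolerance of
`1e-12`; bisection is preferred over Newton iterations because
convergence is unconditional for any valid schedule. `R0 = 1` returns
`r = 0` without iteration, and `R0 = 0` signals an error rather than
returning an infinity. The finite rate is `lambda = exp(r)` and the mean
generation time `T = ln(R0)/r`.

## Daily fates, life expectancy and reproductive value

Life expectancy `e_xj` and reproductive value `v_xj` require knowing
what an individual in class `(x, j)` does overnight. The package
estimates a one-day fate distribution per class from the records
themselves: following each individual in `j` at age `x` to its own state
a day later gives P(stay), P(advance to a successor stage — the pupal
stage splits into female and male with the empirically observed ratio at
each age) and P(die), which sum to 1 by construction. Propagating a unit
of survival mass through these fates and summing it over all later ages
and stages yields

$$e_{xj} = \sum_{i \ge x} \sum_{y} s'_{iy},$$

and discounting the fecundity met along the way at rate `r` yields

$$v_{xj} = e^{r(x+1)} \sum_{i \ge x} e^{-r(i+1)} \sum_y s'_{iy} f_{iy}.$$

Two conventions deserve emphasis because daily-census data leave them
open:

* **Death-day attribution.** `DEAD` is recorded on the day an individual
  was first found dead; it is treated as alive through the preceding
  day. An individual dying between molts belongs to the stage of its
  last living day.
* **Day counting in `e_xj`.** The reference day itself contributes one
  day of life, so a class certain to be found dead at the next census
  has `e = 1`, and a deterministic chain with `k` living days left
  (including today) has `e = k`. The brute-force path-enumeration oracle
  in the test suite encodes the same convention, so the two can only
  agree if both are implemented consistently.

The infinite sums are truncated when the surviving mass drops below
`1e-12` or the propagation runs out of observed transition data
(everyone in the cohort is dead past its maximum age, so the truncation
is exact in practice).

A consequence worth knowing: because `v_xj` is the left eigenvector of
the daily projection recursion, the reproductive-value-weighted
population grows at exactly `lambda` per day from day one. The
acceptance tests use this identity as the sharp form of the
cross-module consistency check between the life-table parameters and the
projection.

## Population projection

`project()` runs the expected-value recursion: real-valued abundances
per (age, stage) class are pushed through the empirical fates each day,
and the eggs laid on day `t` (female abundances times `f_xj`) enter at
age 0 on day `t + 1`, consistent with the `(x+1)` indexing of the
Euler–Lotka equation. Classes older than the oldest observed age of
their stage inherit that stage's last observed fate vector; terminal
stages die one day past their observed maximum, because cohort data
cannot inform older classes. The projection is exactly linear in the
initial egg number.

Because reproduction in these cohorts is concentrated into a few
oviposition days, the projected total shows pronounced cohort cycles
with a period near the generation time that damp slowly: the one-step
growth ratio still oscillates visibly after 200 days. The raw total's
log-slope therefore needs a long burn-in before it settles at `r`; the
tests measure it over days 300–600 of a 600-day projection (about nine
further generations past the third), where it agrees with the
Euler–Lotka root to better than 1%. The defaults (10 initial eggs,
60-day horizon) mirror the classic reporting setup for stage-structure
figures.

## The cohort simulator

`simulate_cohort()` draws individuals independently under a
`sim_config()`:

* **Stage durations** are gamma variates (given mean and shape per
  stage) discretized by mean-preserving stochastic rounding — floor plus
  a Bernoulli on the fractional part — floored at one day. This keeps
  the configured mean exact in expectation, which matters for the
  parameter-recovery tests; `shape = Inf` gives fixed durations.
* **Mortality** is a per-stage daily hazard; an individual surviving all
  its pre-adult days emerges and is assigned female with the configured
  probability. Pre-adult deaths carry unknown sex, exactly as in real
  rearing data, and such individuals count in survival schedules but
  never in fecundity or adult traits.
* **Female reproduction** combines an adult preoviposition period and an
  oviposition-day count (each `1 + Poisson(mean - 1)`), a gamma lifetime
  egg total, and a lognormal rise-then-fall allocation over consecutive
  laying days with largest-remainder rounding, so daily eggs are
  integers summing to the drawn total. The longevity draw is raised to
  APOP + oviposition days when shorter, which biases female longevity
  slightly upward but guarantees a consistent record.

`slitura_config("stem")` and `slitura_config("leaf")` package the
published trait means of *S. litura* on the two asparagus tissues
(per-stage durations, APOP, oviposition days, fecundity, adult
longevities) as simulator targets. Two calibration choices were open and
are ours: duration shapes are set so the individual-level SD matches the
reported standard errors at the study's cohort size of about 100 eggs
(floored at SD 0.35 d so no stage is unrealistically rigid), and a
uniform pre-adult daily hazard is solved from the identity
(survival to adult) x (female fraction) x (mean fecundity) = R₀, using
the tissue's reported R₀, fecundity and mean preadult duration. The
female fraction defaults to 0.5; the published tables do not report sex
ratios or per-trait sample sizes, so both are exposed as free
parameters.

Two caveats on what the simulator does *not* emulate: per-stage means
reported from real cohorts average different survivor sets, so the
printed total larval duration (15.17 d on stems) is a little below the
sum of the printed instar means (15.23 d) — the simulator configures the
per-stage means, and its recovered totals land between the two; and
conditioning on stage completion under a daily hazard shaves a few
hundredths of a day off completed-stage durations. Both effects are an
order of magnitude smaller than the sampling noise at the tested cohort
sizes. Passing recovery tests therefore show the pipeline's estimators
are unbiased for the simulator's world — they cannot certify the
variance or correlation structure of any real cohort, which is also why
the published R₀ and r are not reproduction targets (the raw cohort data
behind them were never deposited).

## Bootstrap inference

The resampling unit is the whole individual record — the only unit that
preserves the within-individual correlation between survival, longevity
and fecundity. Each of `B` replicates redraws `n` records with
replacement and recomputes every parameter from the resampled
net-maternity schedule; the SE is the SD over replicates. Replicates
whose resample contains no reproduction leave `r`, `lambda` and `T`
undefined; they are excluded (not redrawn, which would bias the
resampling distribution) and counted. Replicate-level sub-seeds are
derived deterministically from the master seed, so results do not depend
on execution order. The study-scale default is `B = 1e5`; tests and the
acceptance script use `B` of 2,000–10,000, which is enough to estimate
SEs to a few percent.

The paired bootstrap test draws independent resample pairs, forms the
per-parameter difference, and doubles the smaller tail proportion with a
`+1/(B+1)` continuity guard so p is never exactly zero. The published
tables report letters rather than p-values, and the original program's
tail convention is not printed, so ours is stated rather than claimed
identical. Percentile machinery only; no BCa or studentized intervals.

## Preference assays

Choice counts (larvae per tissue out of `n` released, undecided larvae
allowed) are transformed with `asin(sqrt(p))` — with `p = 0` and `1`
mapped directly, no small-sample correction — then analysed per
observation time by one-way ANOVA with Tukey HSD, in both directions
(tissues within instar, instars within tissue). Letters come from the
maximal cliques of the pairwise non-significance graph, which guarantees
the display is transitive-consistent: groups share a letter exactly when
they are pairwise non-significant at the chosen level. When every group
has zero within-replicate variance, F and p are degenerate; the package
reports `p = 1` for identical means and floors `p` at the smallest
positive double for distinct means, assigning letters from exact mean
comparisons, so the analysis never silently drops a cell.

## Degenerate inputs and numerical notes

* `0/0` in the `m_x` ratio (no survivors) is defined as 0.
* Cohorts with no females yield `R0` but signal on `r`; `r = 0` yields
  `lambda = 1` and an undefined `T`.
* Empty age-stage classes carry no fates and are reported `NA` in
  `e_xj`/`v_xj` rather than extrapolated.
* All validation errors name the offending record and invariant; gaps in
  observation days are errors, never imputed. Censoring (individuals
  lost rather than dead) is not supported.

## Problem sizes used in the tests

The suite exercises cohorts of 1–2,000 individuals (most tests use
40–120, the trait-recovery check 2,000), bootstrap replicate counts of
200–10,000, 200 repeated simulations for interval coverage, and
projections to 600 days. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping the full suite under a
minute.
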