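---
title: "Model, assumptions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, assumptions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iccmcea)
```

## The decision problem

Should Nigeria fund a one-year national programme that trains proprietary
and patent medicine vendors (PPMVs) to diagnose and treat non-severe
childhood pneumonia with amoxicillin dispersible tablets? The package
compares a *no promotion* scenario (current practice: no or wrong
treatment at PPMV shops) with a *promotion* scenario (trained vendors,
respiratory-rate timers distributed), from the payer's perspective, in
2019 USD, with disability-adjusted life years (DALYs) averted as the
effectiveness unit.

## Model structure

A closed cohort of 13.84 million children — the 40% of Nigeria's 34.6 M
under-5s whose caregivers seek care at PPMV shops — starts in the *well*
state and is propagated through a four-state Markov chain (*well*,
*moderate pneumonia*, *severe pneumonia*, *dead*; *dead* absorbing) with a
yearly cycle for 5 cycles. Transition probabilities come from published
national incidence and mortality estimates; yearly rates are converted
with `p = 1 − exp(−r t)`. The three transition rows sum to 1 exactly at
the published values, with a single pneumonia case-fatality probability
(0.0270) shared by the moderate and severe rows.

State occupancy is counted two ways: life-table half-cycle corrected
person-years (`(start + end)/2`, used for discounted person-time exports)
and end-of-cycle membership (used by the calibrated DALY accounting, see
below). Membership itself is propagated uncorrected, the standard
life-table practice.

## The promotion effect

The promotion's clinical benefit is parameterised by the relative risk of
treatment failure under oral amoxicillin, `RR = 0.485`, and the
promotion's effective coverage `s = 0.4338` (uptake difference 49.3% ×
appropriateness 88%). Each targeted transition probability `p` becomes
`p (1 − s (1 − RR))` and the freed mass returns to the recovery
transition of the same row, so rows stay stochastic. Where the effect acts
is *not* uniquely determined by the source material; it is one of the
structural options resolved by the calibration harness (selected: the
moderate→severe progression only).

## DALY accounting

`DALY = YLD + YLL` per cycle, accumulated over the horizon.
`YLD = person-time in state × disability weight` (0.051 moderate, 0.133
severe). `YLL = pneumonia deaths × life-years lost`, with the age band
under-1 in cycle 1 and 1–4 years (life expectancies 54.7 and 57.9)
afterwards. Four YLL modes are implemented: full life expectancy
discounted as an annuity, full life expectancy undiscounted, and horizon
truncation (a death in cycle `c` loses the `n − c + 0.5` years left in the
horizon), optionally discounted.

### Calibrated structural options

The published results table cannot be reproduced from the stated formulas
alone: the DALY magnitudes (≈0.89 M baseline) are two orders below full
life-expectancy YLL accounting, and the cumulative 5-year severe/death
differences are ≈4× the printed 28,359 cases and 900 deaths. The
calibration harness (`calibrate_options()`) therefore runs the
deterministic pipeline over all 4,608 combinations of: effect target set,
coverage scaling, YLD occupancy, DALY discounting, YLL mode,
pneumonia-death eligibility, recurrent-severe counting, and the reporting
convention for averted counts, and scores each by the summed squared
relative error against the six published outputs.

The minimiser — shipped as the package defaults and committed to
`inst/extdata/calibration_report.json` — is: effect on moderate→severe
only with `s = impact`; YLD from end-of-cycle membership, undiscounted;
YLL from severe-state deaths with undiscounted horizon truncation;
recurrent severe episodes not counted as incident; averted deaths and
severe cases reported as the final-cycle (steady-state) annual figure,
matching the published "in a year" framing. Under this set the
deterministic model gives 24,058.6 DALYs averted and an ICER of 143.78 —
within 0.01% of the published 24,061.17 and 143.77 — which is strong
evidence that this is the accounting actually used, even though it
contradicts the stated 5% discounting of effects. Costs are one-off, so
discounting does not arise on the cost side.

Residual discrepancies the calibration cannot remove (documented in the
committed report): baseline and promotion DALY totals land ≈5% below the
published means, and deaths averted (857 deterministic) falls short of the
published 900 under *every* option combination (closest 930). Option sets
that do place the DALY totals inside their published intervals mis-predict
deaths and severe cases by >50% and are correctly rejected.

## Uncertainty

* **Distribution fitting.** Published 95% intervals are converted to a
  standard deviation by the normal approximation `sd = (hi − lo)/3.92`;
  beta and gamma parameters follow by moment matching, the log-normal
  takes `meanlog = log(mean)` (preserving the point estimate; a
  `midpoint` alternative centres the interval instead) and
  `sdlog = (log hi − log lo)/3.92`. Consequence: for the strongly
  right-skewed published intervals (`p_ww`, `p_ms`, `p_ss`) the fitted
  2.5% quantile deviates 10–26% from the published lower bound — the
  published bounds are not normal-approximation-consistent, so exact
  interval recovery is impossible under this (prescribed) fit.
* **Costs.** Components are published with a ±25% band and no family;
  they are drawn uniform on `[0.75, 1.25] × unit cost`. The aggregate
  per-child cost keeps its published gamma (0.22–0.30). Quantities with
  ±10% annotations stay fixed in the PSA.
* **Row repair.** Independent sampling of transition probabilities breaks
  row-stochasticity. The repair is minimal: the drawn death probability is
  kept and the living entries of each row are rescaled to `1 − p_death`
  (the well row is rescaled by its sum); a final ulp-level residual is
  absorbed into the largest entry so row sums are binary-exact.
* **PSA.** 1000 joint draws; both scenarios share each draw. Every draw
  uses a deterministic substream seed derived from the master seed and the
  draw index, so runs are byte-reproducible and draw `i` is invariant to
  the total number of draws. The point ICER is the ratio of means
  (mean ΔC / mean ΔE); per-draw ICERs feed the percentile interval, the
  CE plane and the CEAC.
* **A note on the published intervals.** The published summary intervals
  (±1.5–4.5% of the mean) are numerically consistent with
  ±1.96 × SE-of-the-mean over 1000 draws, not with per-draw percentile
  intervals: the moderate→severe probability alone carries a ±48%
  relative 95% interval, which propagates essentially linearly into DALYs
  averted. This package reports genuine percentile intervals, which are
  accordingly much wider; the PSA *means* are the comparable quantities.
  Relatedly, the PSA mean of DALYs averted sits ≈1.5% below the
  deterministic value, because the fitted log-normal's mean
  `exp(μ + σ²/2)` exceeds the 0.485 point estimate.

## Costing

The ledger multiplies published quantities by unit costs: 58 educators
(49,397 shops / 880 trainees per educator-year, plus 2 reserves) at the
WHO-CHOICE officer salary, 49,397 timers at 44.00 USD, vehicles as a
1,136,400 USD purchase annualised straight-line over 8 years, one-year
life for electronics, plus personnel, welfare and utilities. Two unit
prices are derived, stored explicitly, and flagged at every CLI run: the
refreshments price (5.023612 USD; chosen so the ledger total reproduces
the published mean promotion cost from the published 53,162 refreshment
count) and the inpatient cost per severe admission (39.35 USD; from the
published averted hospitalisation cost, caseload and 35% facility
care-seeking — note this makes the hospitalisation-cost check partly
circular, which is why it is a consistency check rather than a target).

## What the synthetic generator does and does not establish

`random_model()` draws structurally valid parameter sets (Dirichlet-style
rows sharing one death probability, disability weights in (0,1),
protective relative risk, positive costs). Green property tests on these
models establish that the engine conserves the cohort, keeps matrices
stochastic, orders scenarios correctly, and agrees with the
individual-level microsimulation oracle within 3 binomial standard errors
— on *any* valid model, not merely the shipped one. They do not establish
anything about real Nigerian epidemiology: parameter realism lives
entirely in the transcribed input tables.

## Numerical choices

Quantiles use R's type-7 linear interpolation. Discounting is
`(1 + r)^−(cycle − 0.5)` at the cycle midpoint (consistent with half-cycle
occupancy) or `(1 + r)^−cycle` at cycle end. The threshold rounds
`0.52 × 2,230 = 1,159.6` to the nearest 10 (1,160). Zero DALYs averted
makes the ICER undefined; batch code returns `NA` rather than erroring.
Educator requirements round to the nearest integer before adding reserves.

## Known limitations

Single national transition-probability set (no age dependence beyond the
YLL age band); no HIV co-infection or second-line pathways; no correlation
between sampled parameters (independent sampling, as published); currency
conversion upstream of the 2019-USD inputs is out of scope; the
calibrated accounting reproduces the published outputs but inherits their
internal tensions (stated discounting and half-cycle correction vs the
printed magnitudes), which are documented rather than resolved.
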