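---
title: "Phenology-driven pest risk mapping: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-driven pest risk mapping: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorisk)
```

## The model

`phenorisk` implements a deductive, process-based pest-risk pipeline: an
insect's thermal biology — how temperature drives development, survival,
reproduction and aging — is encoded as a set of temperature-response
functions (the *phenology model*), a deterministic cohort is simulated
under reconstructed diurnal temperature cycles, and the resulting daily
life-table parameters are condensed into three mapped indices
(establishment risk ERI, generation index GI, activity index AI).

The central assumptions are:

* **Temperature is the only driver.** Host availability, natural
  enemies, humidity, microclimates (e.g. greenhouses) and photoperiod
  cues are outside the model. Results are *potential* risk under the
  thermal environment alone.
* **The "same shape" development assumption.** Individual variation in
  development time is expressed on *normalized* (physiological) age:
  each individual accumulates age as the integral of the
  temperature-dependent rate, and the distribution of stage-exit ages is
  temperature-invariant (CLL or logit on log normalized age, median at
  1). This is the standard reading that makes a single development-time
  distribution coherent across temperatures.
* **Steady-state daily regimes.** The 365 per-day life-table parameter
  sets treat each day's diurnal cycle as if it persisted for the whole
  cohort life. Daily λ_i, Tc_i and R0_i then have a well-defined meaning
  and enter the index sums independently. The alternative — one
  transient year-long cohort — would entangle the 365 index terms and
  has no clean per-day λ_i; the steady-state convention is what the
  index definitions presuppose.
* **Non-leap 365-day year.** The index formulas hard-code 365 days;
  month lengths are 31, 28, 31, ….

## Function families

Each curve is a `fn_spec(family, params, temp_domain)`. Outside
`temp_domain` evaluation returns the family's boundary behaviour (rate
and fecundity 0, mortality 1) rather than an error, which is what the
cohort engine needs at climatic extremes. Two families deserve comment:

* The published descriptions of this modelling tradition name a "Wang"
  mortality function and an "exponential modified" cumulative-fecundity
  function without printing algebraic forms. `phenorisk` implements the
  mortality contract as a clipped symmetric U,
  `m(T) = 1 − s_opt · exp(−k((T − T_opt)/b)²)`, and cumulative
  egg-laying as `C(x) = 1 − exp(−(a·x + b·x² + c·x³))` over normalized
  female age. Both sit behind the family registry, so an alternative
  parameterization is a registry entry away and nothing in the engine
  changes.
* The Sharpe–DeMichele development rate uses the biophysical
  (Schoolfield-style) form with low- and high-temperature inhibition
  terms in kelvin and R = 1.987 cal mol⁻¹ K⁻¹.

`fit_function()` estimates parameters by bounded Levenberg–Marquardt
least squares with five jittered starts under a fixed seed (thermal
curves have local optima); families with a linearizing transform (CLL,
logit, exponential senescence) are seeded from an exact linear
regression. Non-convergence is a flag in the result, never an
exception; mortality and CDF predictions are clipped to [0, 1] by their
evaluators.

## Diurnal reconstruction and the cohort engine

Within-day temperatures come from the half-day cosine interpolation
(`halfday_temperature()`, 48 15-minute steps per half-day): the first
half-day descends from the day's maximum to its minimum, the second
from the maximum to the *next* day's minimum. With monthly climate
inputs, every day of a month carries that month's values and the last
day's second half-day uses the following month's minimum (December
wraps to January). If a following month's minimum exceeds the current
maximum (possible in steep synthetic seasonality), it is clamped to the
maximum.

`simulate_cohort()` discretises the cohort into K = 25 quantile
sub-cohorts per stage, rank-correlated across stages (the individual at
the p-quantile of egg development is also at the p-quantile of larval
development and adult longevity). Each sub-cohort is deterministic:
physiological age accrues per 15-minute step, survivorship multiplies
`(1 − m(T))^Δt`, adults age along the senescence curve and lay
`F_mean(T) · dC(x)` eggs per step, and die at their longevity quantile.
Stage transitions are resolved at *fractional-step* accuracy in the
compiled kernel, so the scheme converges cleanly in the step size
(15-minute vs 1-minute runs differ in R0 by ~1e-4 relative). Per-step
survival collapses exactly to `1 − m(T)` over a constant-temperature
day by construction of the exponent `Δt = 1/96`.

Numerical choices:

* **K = 25 sub-cohorts** balances quantile resolution against per-cell
  cost; the l_x curves agree with a 1-minute brute-force simulator to
  <1e-3 already at K = 6.
* **Horizon 500 days** with a truncation flag: regimes where
  development never completes (all rates 0) terminate bounded rather
  than erroring, and the flag is carried into the life-table output.
* **Lotka–Euler solver**: bracket expansion from [−2, 2] then bisection
  to interval width 1e-10. Bisection was preferred over Newton because
  near-flat net-maternity schedules make the derivative unreliable.
  R0 = 0 short-circuits to the sentinel r = −∞, λ = 0. At R0 = 1 the
  root is 0 and the doubling time is reported as ∞; Tc falls back to
  the cohort generation time Σx·φ_x/R0 when |r| < 1e-12.
* **Caching**: within a cell, at most 24 distinct (min, max, next-min)
  triples exist (interior vs last day of each month); across cells,
  climates equal to 0.01 °C share one simulation. WorldClim-style grids
  repeat climates massively, so this dominates desk-scale performance.

## The three indices

* **ERI.** The survivable-day indicator reads "possibility for each
  immature stage to survive" as: every immature stage's *daily*
  survival under that day's cycle exceeds a threshold (default 0.01).
  The net-reproduction factor is, by default, the indicator that the
  annual mean R0 reaches replacement (≥ 1), keeping ERI within [0, 1];
  a `capped` alternative (min(1, mean R0)) is exposed for sensitivity
  runs. Class bins are half-open with the top bin closed
  ([0.8, 1.0] = optimal), and ERI > 0.6 flags permanent establishment.
* **GI.** Days where the population cannot replace itself (R0 ≤ 1) or
  where Tc is undefined contribute zero generations; this keeps the
  index bounded and maps deserts/cold regions to GI ≈ 0 instead of
  undefined values.
* **AI.** A single lethal day makes the λ product zero and the log
  −∞; daily λ values are floored at 1e-6 (configurable) before the
  log so lethal regimes map to finite, strongly negative AI. When no
  flooring triggers, 10^AI equals the λ product exactly.

## Geospatial conventions

Rasters are plain matrices with ESRI ASCII georeferencing (lower-left
corner, rows top-down); round trips through `write_ascii_grid()` /
`read_ascii_grid()` are value-identical at 15 significant digits, and
nodata never enters any statistic. Cell areas use a spherical Earth at
111.32 km per degree with a cosine-latitude correction,
`(cellsize·111.32)² · cos(lat)`; against closed-form spherical band
areas this is accurate to well under 0.5%, which is ample for
continental km² bookkeeping. The published continental tables this
package's change bookkeeping mirrors do not state their cell-area
method; the cosine-latitude rule is this package's documented
convention.

## The synthetic generators

`gen_temperature_grid()` emulates only the *structure* the pipeline
assumes of monthly climate grids: a linear latitudinal lapse, a
sinusoidal seasonal cycle peaking mid-July in the northern hemisphere
and mid-January in the southern (the hemispheric phase flip the risk
maps hinge on), a constant diurnal range, and optional Gaussian noise
on the monthly mean. Noise is applied to the mean rather than to min
and max separately, so `max ≥ min` holds by construction. It makes no
attempt to mimic real spatial covariance, orography, continentality or
humidity; passing tests therefore demonstrate pipeline correctness on
plausible gradients, not fidelity to any real climate.

`gen_phenology_model()` produces a complete model with a known optimum:
Sharpe–DeMichele curves for egg and larva (the high-inhibition midpoint
solved numerically so the argmax lands on the requested optimum),
Briere-1 for the pupa (upper threshold placed analytically from the
peak condition), mortality minimal at the optimum and exactly 1 outside
the thermal limits, Gaussian fecundity peaking at the optimum. Defaults
— thresholds 10/22.5/35 °C, peak egg rate 0.2 day⁻¹ (larva and pupa at
0.40 and 0.55 of it), 260 eggs, per-stage survival 0.97 at the optimum,
median adult longevity ~22 days — were chosen once to land the
simulated biology in the realistic range for a warm-climate leafminer
(intrinsic rates ~0.05–0.13 day⁻¹ near the optimum, ~6–8 generations
per year in favourable climates, a 20–25 °C optimal band). The daily
mortality at the thermal thresholds is calibrated to ~0.3 day⁻¹, giving
the flat-bottomed U real stages show, with the jump to 1 beyond the
limits supplied by the domain clamp.

`gen_lifetable_observations()` emulates the classical
constant-temperature laboratory design (five temperatures, replicated):
multiplicative mean-preserving lognormal noise on times, rates and
fecundity, binomial noise (cohorts of 30) on survival — positivity and
bounded probabilities by construction. At `noise_sd = 0` values are
exact, so fit → simulate → fit is an exact fixed point.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic
inputs at desk scale: 20×20 grids (two scenarios), 365-day series,
cohorts of 25 sub-cohorts at 96 steps/day, 100-replicate recovery
designs — sizes chosen so a full run completes in minutes on one CPU
while exercising every code path. Every stochastic step derives from an
explicit seed; pipeline outputs (rasters, CSVs, provenance JSON) are
bit-identical across reruns of the same configuration, which the suite
verifies by checksum.

## Known limitations

* No diapause or overwintering biology: temperate survival is driven
  purely by winter temperatures, which understates persistence of
  species that diapause.
* No density dependence, dispersal, stochasticity or age-structured
  interactions; the cohort is deterministic.
* The steady-state-day convention ignores carry-over between days
  (a cohort born in April experiencing July as it matures); it is the
  convention the index definitions assume, not a transient simulation.
* Monthly climate inputs smooth out day-to-day weather extremes; cold
  snaps shorter than a month are invisible.
* The exact algebraic forms of the "Wang" mortality and "exponential
  modified" cumulative fecundity variants are registry substitutions
  honouring the documented qualitative contracts, not transcriptions of
  the original parameterizations.
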