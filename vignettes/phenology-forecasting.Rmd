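---
title: "Temperature-driven phenology forecasting for woolly apple aphid and its parasitoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-driven phenology forecasting for woolly apple aphid and its parasitoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidphen)
```

## The problem

The woolly apple aphid *Eriosoma lanigerum* is controlled in integrated
apple orchards by a combination of selective insecticides and biological
suppression by its specific parasitoid *Aphelinus mali*. Both the pest's
most vulnerable stage (naked first-instar "crawlers" migrating to flower
clusters and shoots) and the parasitoid's most vulnerable stage (the short
first-generation adult flight in spring) occur in narrow, weather-driven
windows. A grower who sprays a broad-spectrum product during the
parasitoid's first flight can halve the parasitism level for the rest of
the season; a grower who sprays a selective product outside the crawler
migration largely wastes it. `aphidphen` predicts these windows from
temperature records alone.

## The model

Development is modelled with temperature-dependent development rates
$f(T)$ (units: 1/days — the fraction of a full egg-to-adult development
completed per day at temperature $T$). Two families are supported:

* **Saturated polynomials**, $f(T) = c_0 + c_1 T + \dots + c_n T^n$,
  degree 5 for *A. mali* and degree 6 for *E. lanigerum*, fitted to
  literature development times at constant temperatures (10, 13, 15, 18,
  20, 25, 30 °C). These are the package's built-in headline models
  (`amali_model()`, `elanigerum_model()`).
* **Linear degree-day models**, $f(T) = (T - T_{low})/DD$, with
  $T_{low} = 8.3$ °C, $DD = 254.8$ degree-days for *A. mali* and
  $T_{low} = 5.2$ °C, $DD = 267.6$ for *E. lanigerum*. These carry exact
  closed forms and anchor many of the tests.

Rates are clamped to zero below the lower threshold, above the upper
cutoff, and wherever the raw polynomial is negative: development can stall
but never run backwards. Cumulative development
$D(t_k) = D_0 + \sum_{j \le k} f(T_j)\,\Delta t_j$ is summed from
1 January with $\Delta t$ = 1 day (daily data) or 1/24 day (hourly data);
$D$ is measured in generation units.

### Overwintering initialization and events

The start value $D_0$ encodes the overwintering state on 1 January:

* *A. mali* overwinters as a full-grown larva or pupa inside a mummified
  aphid. With egg : larval : pupal development times in the ratio
  1 : 4 : 5, a full-grown larva has completed $(1+4)/(1+4+5) = 50\%$ of
  egg-to-adult development (`stage_fraction_from_ratio()`), so $D_0 = 0.5$.
  First-generation (G1) adults emerge at $D \ge 1$; because females mate
  and oviposit immediately, second-generation (G2) adults follow one full
  generation later, at $D \ge 2$.
* *E. lanigerum* overwinters as first-instar nymphs, so $D_0 = 0$ and the
  first crawler migration is predicted at $D \ge 1$.

Events use the first-crossing convention: the event date is the calendar
date of the first timestep with $D$ at or above the threshold; thresholds
not reached within the series are a valid "not reached" outcome.

### Stochastic cohorts

`simulate_individuals()` runs an individual-based variant: each of $n$
(default 50) individuals draws its per-timestep rate from
$\mathcal{N}(f(T_j), \sigma)$ with $\sigma = 0.015$/day, truncated at
zero. Noise is applied only where the clamped deterministic rate is
positive — otherwise truncated noise would accumulate development through
the winter months below the thresholds, contradicting the zero-development
clamping the deterministic model is built on. With $\sigma = 0$ the cohort
is bit-identical to the deterministic forecast. The headline "first
predicted date" is the earliest individual's crossing (matching how first
field detections behave); median and 10/90 % quantiles are also reported.

## Validation statistics

Predictions are validated against interval-censored field observations:
sticky traps or visual inspections checked every 3–7 days bracket the true
event between the last negative and first positive check, and the working
observed date is the midpoint, rounded toward the earlier day when it
falls on a half day (conservative for spray warnings — assuming an earlier
emergence widens the protection window). Accuracy is quantified by
ordinary least squares of observed on predicted dates, both converted to
days after 31 March (1 April = 1); the ideal model has slope 1, intercept
0, $r^2 = 1$. The p-value is the two-sided $t$-test of the slope on
$n - 2$ df. Because a published "mean error of ± k days" can denote either
the mean absolute or the root-mean-square error, `error_metrics()` reports
MAE, RMSE and the mean signed error, and the acceptance checks pin MAE for
the G1 table and RMSE for the G2 and migration tables — the combinations
consistent with the printed aggregate values.

On the shipped 2010–2020 monitoring tables these statistics come out as
$r^2 = 0.827$ (G1, MAE 4.1 d), $r^2 = 0.683$ (G2, RMSE 5.1 d) and
$r^2 = 0.750$ (migration, RMSE 8.1 d); the G1/G2 $r^2$ published for the
same campaign (0.8498, 0.6897) are not exactly recoverable from
day-rounded tables, consistent with the original regressions having used
unrounded half-day mean dates.

## The synthetic generator

`generate_temperature_series()` emulates an orchard weather-station feed
as mean + seasonal sine + diurnal sine (hourly only) + AR(1) noise.
Defaults describe a temperate Belgian fruit-region year: annual mean
10.5 °C, seasonal half-range 7.5 °C with the minimum in mid-January,
diurnal half-range 4 °C peaking at 14:00, and AR(1) noise with coefficient
0.95 / innovation sd 0.5 °C at hourly resolution (0.7 / 1.5 °C daily),
giving a stationary noise sd near 1.6 (2.1) °C and multi-day weather
systems. These values place G1 emergence in April–early May and crawler
migration in April–May, comparable to the monitoring campaign; they are
configuration, not constants.

`generate_trap_observations()` censors a true event date through a check
schedule: detection is perfect at the first check on or after the event
(a miss-probability hook exists, default 0). A 1-day bracket pins the
event exactly; wider brackets use the floor-midpoint convention above.
`end_to_end_scenario()` chains weather → phenology → censoring →
validation tables for a multi-year campaign.

What a green synthetic test establishes: the pipeline's bookkeeping
(accumulation, clamping, event extraction, censoring, statistics) is
correct, with error budgets matching midpoint-censoring arithmetic
(mean |error| ≈ interval/4). What it does not establish: that the rate
models transfer to any particular orchard — the generator has no cold
snaps, no microclimate, no biological variation between colonies, and
detection is perfect.

## Numerical choices and edge cases

* **Polynomial fitting.** The polynomial is linear in its coefficients, so
  the least-squares optimum is computed by a QR solve on the monomial
  design matrix (the normal equations are numerically singular at degree
  5–6); a Gauss–Newton `nls` pass mirrors the field's usual workflow and
  is kept only when it does not increase the RSS. Exact interpolation
  (e.g. 7 points, degree 6) flags an RSS-underflow warning and reports
  `NA` AIC rather than $-\infty$.
* **AIC.** $n\ln(\mathrm{RSS}/n) + 2k$ with $k$ = coefficients + 1.
  Selection between a degree-2 truth and a degree-5 overfit succeeds with
  probability approaching $P(\chi^2_3 \le 6) \approx 0.89$, never 1; the
  test suite asserts accordingly.
* **Upper cutoff.** `"auto"` finds the first zero crossing above the rate
  maximum to < 0.01 °C (both built-in polynomials cross near 35.0 °C); an
  explicit value overrides it, e.g. to reproduce a literature cutoff such
  as 32.7 °C that is not a root of the rounded printed coefficients. A
  fitted noisy polynomial may not cross zero below the search maximum —
  that is an error asking for an explicit cutoff, not a silent guess.
* **Resolution.** Hourly input is used as-is; daily input uses the daily
  mean temperature (not min/max sine interpolation — the simplest
  defensible reading). Hourly and daily runs of a smooth seasonal series
  agree to < 1 day, but a strong diurnal cycle interacting with the
  thresholds legitimately shifts events by several days between
  resolutions (Jensen effect); hourly is the default.
* **Gaps.** Linear interpolation across ≤ 6 missing hours (hourly) or
  ≤ 1 missing day (daily); anything longer is an error.
* **Leap years** are handled by calendar arithmetic throughout (the
  day-after-31-March index is computed from real dates, never day-of-year
  constants).

## Known limitations

Event *timing* only — no population sizes, no parasitoid–host dynamics,
no diapause or photoperiod effects, and no spatial structure. Model
transfer to other regions is untested: other *A. mali* strains are known
to have lower thresholds and thermal constants. The advisory window
(3-day pre-margin, 8–18-day flight duration) reflects monitoring
experience in one region and is configurable, not biological law.
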