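---
title: "A stock-flow-consistent model of physician supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-flow-consistent model of physician supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physflow)
```

## The model

`physflow` forecasts the head-count of physicians per medical field with a
population-dynamic cohort model that is *stock-flow consistent*: every
change in a stock is an explicit flow, so no physicians appear or vanish
outside the modelled processes. Let `N_i(s, a, t)` be the number of
physicians in field `i` (e.g. general practitioners vs specialists) of sex
`s` and single-year age `a` in year `t`. One model year applies three
processes — entry, aging, exit — which combine into the update equation

```
N_i(s, a+1, t+1) = (1 - gamma(s, a)) * N_i(s, a, t) + p_enter * p_i * Y(s, a+1, t+1)
```

* `gamma(s, a)` is the **effective exit rate**: the probability that a
  physician of that sex and age leaves the workforce within a year, for
  any reason (retirement, emigration, death, change of profession). It is
  shared across fields because the source data report the age/sex
  structure only for all physicians combined.
* `Y(s, a, t)` is the **inflow**: graduates plus immigrating physicians,
  split by sex and spread uniformly over the entry ages 25–34.
* `p_enter` is the probability that a graduate or migrant actually enters
  the modelled workforce; `p_i` is the probability of choosing field `i`
  (`p_GP` and `1 - p_GP` in the two-field model). These two (or, with
  more fields, `1 + K`) numbers are the model's only free parameters.

The modelled age range is 25–74. The youngest age receives only the entry
term; the cohort aging out of 74 is removed (forced exit). Stocks are
continuous (rates are fractional, and all quantities are means), and the
engine is fully deterministic.

The model runs in three phases: **calibration** (the initial year `t0`,
where the state is set equal to the data), **validation** (`t0+1` up to
the last data year, where the iterated model is compared with
observations), and **forecast** (to the horizon, 2040-style).

## Estimation from data

All estimation uses only annual head-count panels of the kind published
by EUROSTAT (stocks by 10-year age group and sex, stocks by field,
graduates, physician immigration, and population projections by
scenario), read from a tidy CSV dialect documented in `?raw_table`.

**Age interpolation.** Counts by 10-year age group are converted to
single-year ages by anchoring each group's mean at its mid-age,
interpolating linearly between adjacent mid-ages, extrapolating flat at
the ends, and then rescaling within each group so the group totals are
conserved exactly. The sources state only that the change between
adjacent groups is linear; the mid-age anchoring and the exact
conservation step are this package's choices. The `<25` and `75+` input
groups are dropped with a warning: an open-ended group cannot support
per-age rates, and entry is modelled at 25–34 anyway.

**Exit rates.** For each cohort we compute the net rate of change
`alpha(s, a, t) = (X(s, a+1, t+1) - X(s, a, t)) / X(s, a, t)` and keep
its exit component, averaged over all years with valid (positive-stock)
observations: `gamma(s, a) = mean_t max(0, -alpha(s, a, t))`. Note the
sign convention: the literature sometimes writes the exit rate as the
negative `alpha` itself; we store the nonnegative magnitude so that the
shrinkage term `(1 - gamma) N` is guaranteed to lie in `[0, N]`. Cells
with no valid observation fall back to **reference rates** estimated from
the pooled (summed) stocks of all countries with complete age/sex data;
countries that report no age/sex stocks at all use the reference rates
and a reference age/sex distribution throughout.

**Inflow.** The forecast inflow level is the unweighted mean of annual
graduates + migrants over a configurable window (default: the last six
data years, 2014–2019 in the canonical setting; a "three most recent
years" mode is available as a config switch, since both conventions are
used in practice). The sex split of entrants is the observed split of the
25–34-year-old stock in the last data year and is applied to graduates
and migrants alike.

## Calibration

`p_enter` and the field-choice probabilities are fitted by minimizing a
weighted chi-squared distance between modelled and observed per-field
totals,

```
chi^2 = sum_i w_i ((Z_i - M_i) / Z_i)^2,   w_i = Z_i / sum_i Z_i,
```

with `Z_i` the observed and `M_i` the modelled total of field `i`. The
default objective evaluates this at the last data year only
(`objective = "final_year"`), exactly as the calibration formula is
usually written; because the fit is also described as being against the
whole observed time series, an `"all_years"` mode (the mean of the
expression over all data years, with year-specific weights) is provided
as a switch. Neither is asserted to be the "true" convention.

Two fitters are provided:

* `calibrate_grid()` — exhaustive search on the `(p_enter, p_GP)` grid in
  steps of 0.01 (101 × 101 evaluations). Deterministic; ties break to the
  lexicographically smallest point.
* `calibrate_gradient()` — projected gradient descent with
  central-difference gradients, Armijo backtracking, Euclidean projection
  onto `[0,1] ×` simplex, and seeded random restarts. This serves the
  many-field generalization where the grid explodes combinatorially.
  "Stochastic" here means the randomized restarts: there is no
  data-subsampling dimension in this objective. On two-field problems it
  agrees with the grid optimum to within grid resolution, which the test
  suite asserts.

**Validation error and its propagation.** Model quality is the per-field
RMSE between model and data over the validation years (`t0+1` to the last
data year — the initial year is excluded because model and data coincide
there by construction). Forecast uncertainty at horizon `h` is
`sigma_i(h) = RMSE_i * sqrt(h)`, i.e. Gaussian propagation under
independent annual increments. The sources do not spell out their
propagation law; the square-root-of-horizon scaling is the simplest model
consistent with error bars that grow with the horizon, and it is stated
here prominently rather than buried.

## Density gaps, significance, and the COVID-19 shock

The forecast is compared with the **constant-density requirement**
`C_i(t) = Z_i(anchor) * pop(t) / pop(anchor)`: the stock needed to keep
physicians-per-population at the anchor-year (last data year) level under
a population scenario. The **density gap** at horizon `T` is

```
DG(T) = (M_i(anchor + T) - C_i(anchor + T)) / (T * Y)
```

with `Y` the constant forecast inflow. `DG` is dimensionless and reads as
the fraction of annual entrants by which the inflow could be reduced
(`DG > 0`, density rising) or should be increased (`DG < 0`) per year to
hold density constant. The annual series for `T = 1 …` horizon is the
primary outcome; summary tables report the terminal horizon (T = 21 for a
2019 anchor and a 2040 horizon). Significance is a two-sided z-test of
`DG` against its propagated standard error
`sigma_DG = sigma_i(T) / (T Y)` (the DG map is linear in `M`), with a
Bonferroni factor equal to the number of hypotheses in the batch
(countries × outcome rows, by default). Alternative population scenarios
(high/low migration or fertility) give an envelope of `DG` values
reported as `DG_min`/`DG_max`.

The **COVID-19 demand shock** inflates the requirement curve to
`C_i(t) * (1 + I(t) * r(t))`, where `I(t)` is the annual probability of
infection and `r(t)` the increased risk of needing outpatient care after
an infection: 20% (hazard ratio 1.2) for 2020–2021 and, due to
vaccination and milder variants, attenuated by 74% to exactly 5.2% from
2022 on. Beyond the last year with infection data, `I(t)` is held at the
last observed level — a conservative worst case. All infections are
assumed detected; a lower detection rate would scale the shock up
proportionally. Reported per field are the mean additional physicians
required per year over the forecast window and the absolute change in the
terminal density gap. Because Table-1-style summaries report one per-year
figure, the mean annual increment is used; a terminal-year or cumulative
convention would be equally defensible and is not asserted to be the
canonical one. When the user supplies no infection history, the default
configuration uses 0.05/0.15/0.30 for 2020/2021/2022 — order-of-magnitude
European case rates — but every test and the acceptance report pass
explicit values.

## The synthetic world

`generate_panel()` emulates the five input table shapes with known ground
truth by running the supply model itself forward from a parametric
initial state. The default spec is the stated world of the test suite:

| quantity | default | why |
|---|---|---|
| observed years | 2000–2019, horizon 2040 | the canonical window |
| total stock | 5 000 | mid-sized European country |
| fields | GP 30% / specialist 70% | typical European split |
| `p_enter`, `p_GP` | 0.9, 0.3 | entry probabilities near one, GP share ~30% |
| exit curve | logistic, half-max 62 y, steepness 0.5/y, plateau 0.30 | near 0 below 50, at plateau by 70, matching empirical exit-rate shapes |
| inflow | 130 graduates + 30 migrants/yr, flat | roughly replaces exits |
| initial pyramid | normal, mean 47 y, sd 10 y | realistic age structure |
| sex | 55% female entrants and stock | mild feminization |
| population | 1e6, +0.2%/yr baseline, +0.7%/−0.3% alternatives | EUROSTAT-like scenario fan |
| observation noise | 1% multiplicative log-normal | counts are positive; errors scale with size |

What a green test establishes: the estimators and the simulator are
mutually consistent (parameter recovery, exit-rate round trips,
conservation laws) in a world whose dynamics *are* the model's. What it
does not establish: anything about real countries — real panels have
series breaks, revisions, definition changes across years, migration
waves and behavioural change, none of which the generator emulates beyond
order of magnitude.

One finding worth stating plainly: when the full estimation pipeline
(group interpolation, then rectified net rates, then calibration) is run
even on *noise-free* grouped synthetic data, the recovered `p_enter` is
biased upward to the boundary at 1. Group interpolation smooths the
pyramid, which distorts cohort-level net rates; the rectification
`max(0, -alpha)` then over-counts exits, and calibration compensates
through the entry probability. Empirical fits of this model family
reporting `p_enter` "close to one" should be read with this mechanism in
mind. The test suite therefore checks noise robustness of the calibrators
given the true dynamics (recovery within ~0.02 at 1% observation noise),
and checks the exact round trips on the single-year ground truth, where
they hold to 1e-6 and better.

## Numerical choices and degenerate inputs

* Grid values are `(0:100)/100`, not `seq(0, 1, 0.01)`, so grid points
  are reproducible bit-for-bit; ties break lexicographically.
* `alpha` with a zero denominator is flagged invalid, never an error;
  `gamma` is clipped to `[0, 1]`; an exit rate above 1 in the simulator
  is an error (it would create negative stocks).
* Interpolation of an all-zero group yields zeros (no 0/0 rescaling).
* Missing (country, year) cells are absent rows, never zeros — zero is a
  legal count; totals rows (`sex = "T"`) are rejected, not summed.
* A zero-length forecast (`forecast_end = last_data_year`) is allowed and
  yields a validation-only run.
* The gradient fitter stops a restart when a backtracking line search
  finds no improvement, and warns (returning the best found) if no
  restart converged.

## Limitations

Beyond the synthetic-vs-real gap above: exit rates are assumed constant
over the forecast and identical across fields; utilisation is not
age-adjusted; head-counts, not full-time equivalents, are modelled; and
the demand side is untouched except for the COVID utilisation shock — a
positive density gap is a statement about density relative to the anchor
year, not about over- or under-supply.
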