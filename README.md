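# physflow

Stock-flow-consistent forecasting of physician supply.

Health-workforce planners need to know whether the current pipeline of
medical graduates will sustain the density of general practitioners and
specialists their population is used to — and how demographic change or a
lasting rise in healthcare utilisation after COVID-19 shifts that
balance. `physflow` implements a population-dynamic cohort model that
answers these questions from publicly available annual head-count panels
alone (EUROSTAT-style tables of physicians by age group and sex, by
field, graduate and migration counts, and population projections), with
no individual-level data and essentially no free parameters.

## The model

The stock `N_i(s, a, t)` of physicians in field `i`, sex `s`, single-year
age `a ∈ [25, 74]` evolves by one update per calendar year:

    N_i(s, a+1, t+1) = (1 − γ(s,a)) · N_i(s, a, t) + p_enter · p_i · Y(s, a+1, t+1)

- `γ(s, a)` — effective exit rate, estimated from the data as the
  year-averaged exit component of cohort net rates of change,
  `γ(s,a) = mean_t max(0, −α(s,a,t))` with
  `α = (X(s,a+1,t+1) − X(s,a,t)) / X(s,a,t)`;
- `Y` — annual inflow (graduates + migrating physicians), split by sex
  and spread over entry ages 25–34;
- `p_enter`, `p_i` — the only free parameters: the probability of
  entering the workforce and of choosing field `i`. They are calibrated
  against the observed per-field totals by minimising the weighted
  chi-squared distance `χ² = Σ_i w_i ((Z_i − M_i)/Z_i)²`,
  `w_i = Z_i / Σ Z_i`, by exhaustive 0.01-step grid search (two fields)
  or projected gradient descent with seeded restarts (any number of
  fields).

The forecast is compared with the constant-density requirement
`C_i(t) = Z_i(2019) · pop(t)/pop(2019)`; the **density gap**
`DG(T) = (M_i(2019+T) − C_i(2019+T)) / (T · Y)` expresses the surplus or
deficit as the fraction of annual entrants to remove (`DG > 0`) or add
(`DG < 0`) per year. A COVID-19 demand shock inflates the requirement by
`(1 + I(t)·r(t))` — infection probability times the increased
outpatient-care risk after infection (20% in 2020–2021, attenuated by 74%
to 5.2% from 2022).

See `vignettes/physician-supply-model.Rmd` for the full account of the
methods, defaults, and limitations.

## Worked example

A synthetic mid-sized country (~5 000 physicians, 30% GPs, true
`p_enter = 0.9`, `p_GP = 0.3`, 1% observation noise) run through the full
pipeline — interpolation, exit-rate estimation, grid calibration,
forecast to 2040, density gaps with a COVID shock:

```r
library(physflow)
world <- generate_panel(synthetic_spec(seed = 42))
cfg <- country_config("SY", t0 = 2000, last_data_year = 2019,
                      forecast_end = 2040)
res <- run_country(world$tables, cfg, covid = covid_shock_config())
res$fit
#> <fit_result [grid/final_year] chi2=4.640e-03 p_enter=1.000 p=[GP=0.310, specialist=0.690]>
res$run
#> <model_run SY 2000-2040: GP=1470, specialist=3274>
res
#> <country_result SY chi2=4.640e-03>
#>   country      field  T      DG sigma_DG p_value  DG_min DG_max
#> 1      SY         GP 21 -0.0172    0.120       1 -0.0673 0.0282
#> 2      SY specialist 21 -0.0740    0.299       1 -0.1896 0.0305
#> 3      SY        all 21 -0.0912    0.322       1 -0.2568 0.0587
#>   covid_additional_per_year covid_delta_DG
#> 1                      24.0        0.00709
#> 2                      55.3        0.01636
#> 3                      79.3        0.02345
```

Reading the report: the calibrated field split (31% GP) matches the
generating truth to one grid step; `p_enter` lands on the boundary — a
known upward bias of the grouped-data pipeline discussed in the vignette.
The density gap for all physicians is −9.1% of annual inflow at the 2040
horizon (supply falls ~9% of a graduating cohort per year short of
constant density), not significant against the propagated validation
RMSE (`p = 1`). The COVID shock would require on average ~79 additional
physicians per year and deepens the gap by 2.3 points — small against
the forecast uncertainty, mirroring the qualitative finding that
demographic change dominates the pandemic's long-run effect on physician
demand.

Real EUROSTAT extracts can be run by exporting them to the documented
CSV schema (`?raw_table`) and calling the same functions, or via the CLI:

```sh
Rscript inst/cli/physflow.R simulate --seed 42 --out-dir synth/
Rscript inst/cli/physflow.R run --config cfg.json --dir synth/ --out-dir out/
```

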