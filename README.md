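# tempburden

Estimate the mortality burden of non-optimal ambient temperature from
multi-location daily time series.

Heat and cold both kill, with effects that are non-linear in temperature
and distributed over days to weeks. `tempburden` implements the standard
two-stage design used for national and multi-country temperature–mortality
studies, aimed at epidemiologists and biostatisticians working with daily
death counts and reanalysis-derived weather series:

1. **Stage 1 — per-location DLNM.** For each location, a quasi-Poisson
   time-series regression with a distributed-lag non-linear model:
   log μ<sub>t</sub> = α + s(time) + dow + γ·RH +
   Σ<sub>j,k</sub> θ<sub>jk</sub> w<sub>jk,t</sub>, where
   w<sub>jk,t</sub> = Σ<sub>ℓ</sub> b<sub>j</sub>(x<sub>t−ℓ</sub>)
   c<sub>k</sub>(ℓ) is the cross-basis of a cubic B-spline of temperature
   (knots at the location's 10th/75th/90th percentiles) and a natural
   cubic spline of lag (0–7 days by default; 14/21/28 as sensitivity).
   The fitted surface is reduced to the overall cumulative
   exposure–response curve by summing over lags.
2. **Stage 2 — multivariate meta-regression.** Reduced coefficient
   vectors are pooled across locations under
   β̂<sub>i</sub> ~ N(X<sub>i</sub>θ, Ψ + S<sub>i</sub>) with seven
   location-level meta-predictors, Ψ estimated by REML; Cochran Q / I²
   summarize residual heterogeneity, Wald χ² tests each predictor, and
   location curves are refined as BLUPs.
3. **MMT and attribution.** Each location's minimum mortality temperature
   (MMT) is the arg-min of its BLUP curve on the percentile grid 1–99;
   backward attribution converts each day's cumulative log relative risk
   relative to the MMT into attributable deaths,
   AN<sub>t</sub> = Y<sub>t</sub>(1 − e<sup>−η</sup>), split into cold and
   heat days and extreme-percentile bands, with Monte-Carlo empirical 95%
   intervals.

A synthetic-data generator (`sim_scenario()` / `simulate_scenario()`)
produces multi-location datasets with a fully known exposure–lag–response
truth, so the entire pipeline can be validated against recoverable
targets. Helpers convert hourly temperature/dewpoint records to daily
series (August–Roche–Magnus relative humidity, UTC-offset day definition).

## Worked example

Simulate the standard preset (32 locations × 10 years, J-shaped truth with
its minimum at the 25th percentile and a true national attributable
fraction of 2.4%), run the full two-stage analysis, and read off the
burden (a couple of minutes on one CPU):

```r
library(tempburden)

sim <- simulate_scenario(sim_scenario(seed = 42))   # 32 locations x 10 years
cfg <- run_config(max_lag = 7, season_df_per_year = 6, n_sim = 500, seed = 1)
res <- run_two_stage(sim$series, sim$meta_predictors, cfg)

print(res)
#> <result_bundle> 32 locations, lag 0-7
#>   I2 = 7.1% | country AF total 2.51% (cold 0.82%, heat 1.69%)

print(res$country)
#> <attribution_result> 2,222,686 deaths, n_sim = 500
#>  category    an an_low an_high   af af_low af_high   days
#>     total 55684  48981   61213 2.51   2.20    2.75 116864
#>      cold 18126  15915   20155 0.82   0.72    0.91  41635
#>      heat 37558  32454   42111 1.69   1.46    1.89  75229
#>        p1  1019    890    1139 0.05   0.04    0.05   1184
#>        p5  4177   3703    4602 0.19   0.17    0.21   5856
#>       p10  7227   6441    7952 0.33   0.29    0.36  11712
#>       p90  9543   8368   10587 0.43   0.38    0.48  11712
#>       p95  5072   4460    5620 0.23   0.20    0.25   5856
#>       p99  1098    941    1243 0.05   0.04    0.06   1184
```

Reading the output: across 2.22 million simulated deaths, 2.51%
(95% empirical CI 2.20–2.75) are attributable to non-optimal temperature —
0.82% to cold days and 1.69% to heat days (the truth, 2.4%, known here by
construction, sits inside the interval; total = cold + heat exactly). Days
hotter than the 95th percentile alone account for 0.23%. Per-location
results live in `res$location_table`:

```r
head(res$location_table[, c("location", "mmt", "mmp",
                            "af_total", "af_cold", "af_heat")])
#>   location  mmt mmp af_total af_cold af_heat
#> 1   loc_01 25.7  34     1.86   0.511    1.35
#> 2   loc_02 26.6  44     1.76   0.728    1.03
#> 3   loc_03 15.5  22     3.44   0.682    2.76
#> 4   loc_04 23.9  28     2.85   0.909    1.94
#> 5   loc_05 21.5  35     2.30   0.830    1.47
#> 6   loc_06 20.0  45     2.52   0.873    1.64
```

`sensitivity_grid()` re-runs the analysis over lag windows (7/14/21/28),
seasonality df (4/6/8), period strata, or PM2.5 adjustment, and tabulates
the attributable fractions per variant. `write_results()` emits all tables
as delimited text; `inst/cli/tempburden.R` wraps `simulate` / `run` /
`sensitivity` for shell use.

Real data enter through `read_daily_series()` (long-format delimited text
with columns `location`, `date`, `deaths`, `tmean`, `rh`[, `pm25`]) and,
for hourly weather, `read_hourly()` + `daily_aggregate()`.

See the vignette (`vignettes/two-stage-temperature-mortality.Rmd`) for the
model details, the generator's design, numerical choices, and known
limitations.

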