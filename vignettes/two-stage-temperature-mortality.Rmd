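---
title: "Two-stage distributed-lag analysis of temperature and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage distributed-lag analysis of temperature and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`tempburden` estimates how daily all-cause mortality responds to daily mean
temperature across a set of locations, and how many deaths are attributable
to non-optimal (cold and hot) temperatures. It follows the established
two-stage design for multi-location time-series studies.

## Stage 1: per-location quasi-Poisson DLNM

For each location, daily death counts $Y_t$ are modelled as overdispersed
Poisson with log link:

$$\log \mu_t = \alpha + s(\text{time}_t) + \delta_{\mathrm{dow}(t)}
  + \gamma \,\mathrm{RH}_t + \sum_{j,k} \theta_{jk}\, w_{jk,t},$$

where $w_{jk,t} = \sum_{\ell=0}^{L} b_j(x_{t-\ell})\, c_k(\ell)$ is the
DLNM *cross-basis*: the tensor product of an exposure basis $b_j$ (a cubic
B-spline of temperature with interior knots at the 10th, 75th and 90th
percentiles of the location's own temperature distribution, boundary knots
at its observed range) and a lag basis $c_k$ (a natural cubic spline with
intercept over the integer lags $0..L$). Seasonality and long-term trend
are controlled by a natural cubic spline of the day index with 6 df per
year (total df rounded over the series length); day-of-week enters as six
indicators with Monday as the reference; relative humidity as a same-day
linear term; PM2.5 optionally likewise.

Coefficients are the Poisson maximum-likelihood estimates (IRLS via
`stats::glm.fit`, deviance tolerance $10^{-10}$, at most 50 iterations);
the covariance is scaled by the Pearson dispersion
$\hat\phi = \sum_t (y_t-\hat\mu_t)^2/\hat\mu_t \,/\, (n-p)$. The first $L$
days (incomplete exposure history) and days with missing data are dropped
from the likelihood; lags are always computed on the calendar grid so a
dropped day never silently shortens another day's history.

The fitted surface is *reduced* to the overall cumulative
exposure-response curve by summing over lags: with $u_k = \sum_\ell
c_k(\ell)$, the reduced coefficients are $\beta_j = \sum_k u_k
\theta_{jk}$, a linear map whose covariance transform is exact. Curves are
fitted uncentred and re-centered at prediction time — log-RR differences
do not depend on the centering — so no second fitting pass is needed once
the minimum mortality temperature is known.

## Stage 2: multivariate meta-regression and BLUPs

The per-location reduced coefficient vectors $\hat\beta_i \in
\mathbb{R}^q$ are pooled with a multivariate random-effects
meta-regression

$$\hat\beta_i \sim N(X_i \theta,\; \Psi + S_i),$$

where $S_i$ is the stage-1 covariance, $\Psi$ the between-location
covariance, and $X_i$ carries an intercept plus the location-level
meta-predictors (average temperature, temperature range,
population-weighted latitude and elevation, population density, average
relative humidity, and a multidimensional poverty index). $\Psi$ is
estimated by REML over a Cholesky parameterization (BFGS, relative
tolerance $10^{-10}$, start $\Psi = 0.1\,\overline{S}$; a simplex polish is
added when $\Psi$ has at most 3 free parameters so the scalar case reaches
oracle precision); fixed effects are profiled out by GLS. Meta-predictors
are standardized internally and effects reported on the original scale.

Heterogeneity is summarized by the multivariate Cochran $Q$ (residual
weighted sum of squares of the fixed-effects-only fit), its df
$(k-p-1)q$, and $I^2 = \max(0, (Q - \mathrm{df})/Q) \times 100$. Each
meta-predictor gets a Wald $\chi^2_q$ test on its $q$ coefficients.
Location-specific curves are refined as best linear unbiased predictions,
$\mathrm{BLUP}_i = X_i\hat\theta + \Psi(\Psi+S_i)^{-1}(\hat\beta_i -
X_i\hat\theta)$, whose covariance combines the conditional variance with
the propagated fixed-effect uncertainty.

A note on scales: coefficients sit on location-relative bases (percentile
knots of each location's own temperature distribution). Pooling them as-is
is the standard two-stage convention; it means the pooled coefficients
describe curves in *relative* (percentile-anchored) temperature space, and
location curves are always evaluated against their own basis.

## MMT and attributable burden

The minimum mortality temperature (MMT) of each location is the arg-min of
its BLUP curve over the empirical temperature percentiles 1–99 (type-7
quantiles); ties break toward the median percentile and monotone curves
are flagged as boundary solutions (percentile 1 or 99). No sub-percentile
refinement is applied by default.

Attribution is *backward*: the deaths of day $t$ are attributed to the
exposure history $x_{t-L}, \dots, x_t$. Because stage 2 pools only the
reduced curve $f$, per-lag contributions are not recoverable, and the
cumulative log-RR of the history is reconstructed by allocating $f$
uniformly over the window:

$$\eta_t = \frac{1}{L+1}\sum_{\ell=0}^{L} f(x_{t-\ell}), \qquad
  \mathrm{AN}_t = Y_t\,(1 - e^{-\eta_t}).$$

Summed over the series, this reproduces the true cumulative contribution
for *any* true lag-weight profile that sums to one (each day's $f$ value
is counted exactly once across windows), whereas the common alternative —
evaluating $f$ at the window-mean exposure — is biased downward for convex
curves by a Jensen gap. Days at exactly the MMT contribute zero; the
protective side of the curve yields negative attributable numbers, so
per-category totals can be negative. Cold and heat are the days with mean
temperature below and above the MMT; extreme bands (beyond the
1st/5th/10th and 90th/95th/99th percentiles) are nested within them.
$\mathrm{AN}_{\mathrm{total}} = \mathrm{AN}_{\mathrm{cold}} +
\mathrm{AN}_{\mathrm{heat}}$ holds exactly.

Confidence intervals are empirical: `n_sim` (default 1000) coefficient
vectors are drawn from the multivariate normal of the BLUP, the full daily
attribution is recomputed per draw, and the 2.5th/97.5th percentiles of
the category totals are reported. Country totals sum locations per draw
(independent across locations), so aggregated intervals are coherent with
the per-location ones. A seed is mandatory.

## Preprocessing

Hourly temperature/dewpoint records are converted to daily series by (1)
computing relative humidity pointwise with the August–Roche–Magnus
approximation, $\mathrm{RH} = 100\, e^{a t_d/(b+t_d)} / e^{a t/(b+t)}$
with $a = 17.625$, $b = 243.04\,^\circ$C (a common parameterization; the
constants are exposed), clipped to $[0, 100]$; and (2) averaging within
calendar days defined after shifting timestamps by a fixed UTC offset
($-5$ h for Colombia). RH is averaged *after* the pointwise conversion:
because the formula is non-linear, RH of the daily means differs (Jensen
gap), and the package deliberately uses the mean of hourly RH. Days with
under 75% of their expected records are flagged missing.

# The synthetic-data generator

`sim_scenario()` / `simulate_scenario()` generate multi-location data with
a fully known truth so that every stage has a recoverable target. Per
location: temperature is a seasonal sinusoid plus stationary AR(1) noise
(defaults: mean drawn from 12–28 °C, half-amplitude 0.5–2.5 °C — weak,
near-equatorial seasonality — AR coefficient 0.7); baseline mortality is
log-linear with a long-term trend, mild seasonality, day-of-week effects,
and a log-normal location intercept (median 15 deaths/day); counts are
negative-binomial with size $\mu/(\phi-1)$ so a correctly specified fit
has Pearson dispersion near the target $\phi$ (default 1.3; quasi-Poisson
itself has no generative form).

The true risk surface is piecewise-quadratic in the exposure *percentile*
$u$, zero at the minimum $u_0$ (default percentile 25) and rising to
`logrr_cold` at $u=0$ and `logrr_heat` at $u=1$ (defaults 0.08 and 0.07,
chosen so national attributable fractions land near 0.7% cold / 1.8% heat
— the magnitudes reported for tropical, heat-dominant settings). The
surface is spread over lags by cold/heat weight vectors summing to one
(default: exponential decay, mean lag ≈ 2 days). Location covariates are
drawn once per scenario; the curve amplitude is modified by standardized
population-weighted elevation (log-scale coefficient 0.25) plus a small
location-level log-normal perturbation (SD 0.05, matching the very low
residual heterogeneity such analyses report). The simulation truth —
per-location true curve on the percentile grid, true MMT/MMP, and true
attributable numbers obtained by applying the true surface with its true
lag weights to the generated history — is computed by direct arithmetic,
never through the fitting code.

`sim_scenario_cold_lagged()` is a variant whose cold arm acts with a
delayed, persistent lag profile over 0–28 days (peak near lag 10) while
heat stays acute, and whose temperature has multi-week persistence
(AR 0.95) so that delayed cold impacts fall on climatologically cold days
— the regime in which extending the lag window raises the cold burden
while the heat burden stays put.

What the generator does *not* emulate: spatial correlation of climate
across locations, demographic structure, reporting artifacts, multi-modal
or skewed temperature distributions, and harvesting (short-term mortality
displacement). Passing tests on synthetic data therefore validate the
estimation machinery under a known, well-behaved truth; they do not
certify the epidemiological assumptions on any particular real dataset.

# Numerical and design choices

- **Quantile definition.** All percentile computations (knots, percentile
  tables, MMT grid) use type-7 (linear interpolation) quantiles; knot
  values shift slightly across definitions, so one is fixed and
  documented.
- **Exposure-spline degree.** Cubic by default (`var_degree`), matching
  common practice; configurable.
- **Boundary knots** default to the observed range of each location's
  temperature series. B-spline evaluation outside the boundary errors
  unless explicitly clamped to the boundary (used when re-evaluating
  curves on percentile grids).
- **Lag knots** are placed at equal spacing on the $\log(\ell+1)$ scale —
  2 interior knots for lag 0–7 (giving knots at 1 and 3 days), 3 for
  longer windows — overridable. The lag basis keeps its intercept so the
  lag-0 effect is representable; `lag_df = knots + 2`.
- **Estimation method.** REML by default (ML available); meta-predictors
  standardized internally for optimizer stability.
- **Degenerate inputs.** Rank-deficient designs error naming the aliased
  columns; duplicated meta-predictors error rather than alias; monotone
  curves return a flagged boundary MMP; locations that fail stage 1 are
  excluded from stage 2 with a warning, and fewer than three usable
  locations abort.
- **Determinism.** Bases are pure functions of their inputs; identical
  config and seed reproduce byte-identical output tables.

## Problem sizes used by the test suite

The packaged experiments are sized to run comfortably on one CPU: the
standard preset (32 locations × 10 years) takes a few seconds per
replicate, so the recovery experiment uses 24 replicates with
`n_sim = 500`; the Wald-calibration experiment uses 1000 scalar-outcome
replicates at $k = 32$; the directional lag experiment runs the four
standard windows once. These sizes are the package's own choices and are
stated here so they can be scaled up by users who want tighter Monte-Carlo
error.

# Known limitations

- **Curve-shape approximation bias.** The default synthetic truth is
  quadratic in the exposure *percentile*; mapped to the temperature scale
  this is not representable by a cubic B-spline with knots at the
  10th/75th/90th percentiles. Averaged over replicates the fitted overall
  curve under-shoots the truth by roughly 10–25% in the mid-range and near
  the 99th percentile, and the national attributable fraction by roughly
  10%. This is a genuine property of the estimator under this truth — not
  a coding artifact (truths that lie in the spline space are recovered
  essentially unbiasedly) — and it is why the packaged coverage experiment
  reports empirical 95% intervals covering the true burden at slightly
  below the nominal rate.
- **MMT identifiability.** A J-shaped curve is nearly flat on the heat
  side of its minimum: at realistic effect sizes the arg-min is weakly
  identified and per-location MMP estimates spread over tens of
  percentiles (real analyses show the same spread, reporting MMPs from 1
  to 99). The packaged recovery experiment shows the median MMP landing
  about 5–10 percentiles warm of the truth; MMT/MMP values should be read
  with that uncertainty in mind.
- **Wald calibration.** The meta-regression Wald test has close-to-nominal
  size under the low-heterogeneity conditions these analyses report
  (measured 4.5% at $k=32$), but inflates as $\tau^2$ grows relative to
  the within-location variances (measured ~7% at $I^2 \approx 30\%$) — the
  familiar small-$k$ anticonservatism of variance-component Wald tests.
- **Attribution with lagged effects.** Cold/heat classification is by each
  day's own temperature. When true effects are strongly delayed and the
  temperature series has short memory, contributions of cold exposures
  can surface on warmer days and be counted as heat; with realistic
  multi-week cold spells this leakage is small.
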