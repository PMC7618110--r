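# Shared fixture builders: everything is generated in code at test time.

# A small, fast scenario: few locations, short series, no effect modifiers.
tiny_scenario <- function(seed, k = 4L, years = 2L, ...) {
  sim_scenario(k = k, years = years, seed = seed,
               gamma_elevation = 0, between_sd = 0, ...)
}

# A single-location daily series with a known data-generating process and
# moderate counts; returns both the series and the simulation truth.
tiny_location <- function(seed, years = 3L, baseline_log_mean = log(60),
                          ...) {
  sc <- sim_scenario(k = 1L, years = years, seed = seed,
                     gamma_elevation = 0, between_sd = 0,
                     baseline_log_mean = baseline_log_mean,
                     baseline_log_sd = 0, ...)
  sim <- simulate_scenario(sc)
  list(series = sim$series[[1L]], truth = sim$truth[[1L]], scenario = sc)
}

# Deterministic exposure basis on [0, 30] with mid-range knots.
demo_var_spec <- function(intercept = FALSE, degree = 3L) {
  basis_spec("bspline", interior_knots = c(8, 18, 24),
             boundary_knots = c(0, 30), degree = degree,
             intercept = intercept)
}

# Lag spline over 0..L with the package's log-scale knot rule.
demo_lag_spec <- function(L = 7L, n_knots = 2L) {
  basis_spec("natural_cubic",
             interior_knots = tempburden:::log_lag_knots(L, n_knots),
             boundary_knots = c(0, L), intercept = TRUE)
}

demo_cb_spec <- function(L = 7L) {
  crossbasis_spec(demo_var_spec(), demo_lag_spec(L), L)
}

# Random PSD matrix of dimension q.
random_psd <- function(q, scale = 1) {
  A <- matrix(stats::rnorm(q * q), q)
  scale * (tcrossprod(A) / q + diag(1e-3, q))
}
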