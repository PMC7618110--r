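make_series <- function(seed = 1, years = 2) {
  tiny_location(seed, years = years)$series
}

test_that("design matrix has the documented block structure", {
  s <- make_series()
  n <- nrow(s)  # 2 years: 730 or 731 days
  des <- build_design(s, stage1_config())
  # intercept 1 + crossbasis 6*4 + season round(6 * n/365.25) + dow 6 + rh 1
  season_df <- round(6 * n / 365.25)
  expect_equal(ncol(des$X), 1 + 24 + season_df + 6 + 1)
  expect_equal(season_df, 12)
  expect_named(des$blocks, c("intercept", "crossbasis", "season", "dow", "rh"))
  expect_equal(length(des$blocks$crossbasis), 24L)
  # block indices partition the columns
  expect_equal(sort(unname(unlist(des$blocks))), seq_len(ncol(des$X)))
})

test_that("day-of-week block is a proper indicator set with Monday reference", {
  s <- make_series()
  des <- build_design(s, stage1_config())
  dow_block <- des$X[, des$blocks$dow, drop = FALSE]
  expect_true(all(rowSums(dow_block) %in% c(0, 1)))
  mondays <- format(s$date, "%u") == "1"
  expect_true(all(rowSums(dow_block)[mondays] == 0))
  expect_true(all(rowSums(dow_block)[!mondays] == 1))
})

test_that("covariate toggles remove exactly their own columns", {
  s <- make_series()
  with_rh <- build_design(s, stage1_config(use_rh = TRUE))
  no_rh <- build_design(s, stage1_config(use_rh = FALSE))
  expect_equal(ncol(with_rh$X) - ncol(no_rh$X), 1L)
  expect_false("rh" %in% names(no_rh$blocks))
  shared <- intersect(colnames(with_rh$X), colnames(no_rh$X))
  expect_equal(with_rh$X[, shared], no_rh$X[, shared])
  expect_error(build_design(s, stage1_config(use_pm25 = TRUE)), "pm25")
})

test_that("intercept-only quasi-Poisson fit recovers log of the mean", {
  set.seed(101)
  y <- rpois(500, 7)
  fit <- fit_quasipoisson(y, matrix(1, 500, 1))
  expect_equal(unname(fit$coef), log(mean(y)), tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("Pearson dispersion is near 1 for equidispersed Poisson data", {
  set.seed(102)
  n <- 5000
  x <- rnorm(n)
  mu <- exp(1.5 + 0.3 * x)
  y <- rpois(n, mu)
  fit <- fit_quasipoisson(y, cbind(1, x))
  expect_gt(fit$dispersion, 0.9)
  expect_lt(fit$dispersion, 1.1)
})

test_that("IRLS coefficients match an independent optimizer on a toy model", {
  set.seed(103)
  n <- 100
  X <- cbind(1, rnorm(n), runif(n))
  y <- rpois(n, exp(drop(X %*% c(1, 0.4, -0.6))))
  fit <- fit_quasipoisson(y, X)
  nll <- function(b) sum(exp(drop(X %*% b))) - sum(y * drop(X %*% b))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coef), opt$par, tolerance = 1e-6)
})

test_that("rank deficiency is reported with the offending column names", {
  set.seed(104)
  X <- cbind(a = 1, b = rnorm(20), dup = 0)
  X[, "dup"] <- X[, "b"]
  expect_error(fit_quasipoisson(rpois(20, 5), X), "dup")
})

test_that("vcov reduces to the plain Poisson information inverse at phi 1", {
  set.seed(105)
  n <- 300
  X <- cbind(1, rnorm(n))
  y <- rpois(n, exp(drop(X %*% c(2, 0.2))))
  fit <- fit_quasipoisson(y, X)
  expect_equal(fit$vcov / fit$dispersion, fit$vcov_unscaled)
  # independent information computation at the fitted coefficients
  mu <- exp(drop(X %*% fit$coef))
  info <- t(X) %*% (X * mu)
  expect_equal(unname(fit$vcov_unscaled), unname(solve(info)),
               tolerance = 1e-6)
})

test_that("a null temperature effect yields a flat reduced curve", {
  loc <- tiny_location(seed = 6, years = 3,
                       logrr_cold = 0, logrr_heat = 0)
  fit <- fit_location(loc$series, stage1_config())
  pt <- fit$percentile_table
  pred <- predict_curve(fit$reduced, pt, center = pt[50], clamp = TRUE)
  # jointly flat: nowhere beyond 3 pointwise SEs of zero
  expect_true(all(abs(pred$logrr[-50]) < 3 * pred$se[-50] + 1e-12))
})

test_that("period stratification equals fitting the truncated series", {
  loc <- tiny_location(seed = 7, years = 4)
  s <- loc$series
  yr <- as.integer(format(s$date, "%Y"))
  sub <- s[yr <= 2011, ]
  attr(sub, "location_id") <- attr(s, "location_id")
  class(sub) <- class(s)
  f_direct <- fit_location(sub, stage1_config())
  f_pipe <- tempburden:::subset_period(s, c(2010, 2011))
  expect_equal(fit_location(f_pipe, stage1_config())$reduced$coef,
               f_direct$reduced$coef)
})

test_that("reduced predictions are invariant to the centering convention", {
  loc <- tiny_location(seed = 8, years = 2)
  fit <- fit_location(loc$series, stage1_config())
  pt <- fit$percentile_table
  grid <- pt[c(1, 25, 50, 75, 99)]
  a <- predict_curve(fit$reduced, grid, center = pt[50], clamp = TRUE)
  b <- predict_curve(fit$reduced, grid, center = pt[10], clamp = TRUE)
  shift <- predict_curve(fit$reduced, pt[50], center = pt[10],
                         clamp = TRUE)$logrr
  expect_equal(a$logrr, b$logrr - shift, tolerance = 1e-12)
})

test_that("fit_location requires a usable year of data", {
  loc <- tiny_location(seed = 9, years = 2)
  short <- loc$series[1:200, ]
  attr(short, "location_id") <- "short"
  class(short) <- class(loc$series)
  expect_error(fit_location(short, stage1_config()), "one year")
})

test_that("daily_series validates dates, counts and lengths", {
  d <- seq(as.Date("2010-01-01"), by = "day", length.out = 10)
  expect_error(daily_series("a", d[-3], rep(1, 9), rep(20, 9), rep(70, 9)),
               "consecutive")
  expect_error(daily_series("a", d, rep(-1, 10), rep(20, 10), rep(70, 10)),
               "non-negative")
  expect_error(daily_series("a", d, rep(1, 9), rep(20, 10), rep(70, 10)),
               "length")
  s <- daily_series("a", d, rep(1, 10), rep(20, 10), rep(70, 10))
  expect_s3_class(s, "daily_series")
})

test_that("daily series round-trip through the long-format text file", {
  loc1 <- tiny_location(seed = 10, years = 2)$series[1:30, ]
  attr(loc1, "location_id") <- "A"; class(loc1) <- c("daily_series", "data.frame")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_daily_series(list(loc1), path)
  back <- read_daily_series(path)[[1]]
  expect_equal(back$deaths, loc1$deaths)
  expect_equal(back$tmean, loc1$tmean, tolerance = 1e-12)
  expect_equal(back$date, loc1$date)
})
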