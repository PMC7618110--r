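make_curve <- function(coef, vcov = diag(1e-6, length(coef)),
                       spec = demo_var_spec()) {
  structure(list(coef = coef, vcov = vcov, var_spec = spec, center = NULL),
            class = "reduced_curve")
}

# percentile table of a temperature series concentrated on [0, 30]
flat_pt <- function() {
  stats::quantile(seq(0, 30, length.out = 1000), 1:99 / 100, type = 7)
}

test_that("a symmetric U-curve puts the MMT at the median percentile", {
  spec <- demo_var_spec()
  pt <- flat_pt()
  # least-squares projection of a symmetric parabola onto the basis
  B <- eval_basis(pt, spec, clamp = TRUE)
  target <- ((pt - unname(pt[50])) / 15)^2
  coef <- qr.solve(B, target)
  m <- find_mmt(make_curve(coef), pt)
  expect_equal(m$mmp, 50L, tolerance = 1L)
  expect_false(m$boundary)
})

test_that("a monotone curve hits a boundary percentile and is flagged", {
  spec <- demo_var_spec()
  pt <- flat_pt()
  B <- eval_basis(pt, spec, clamp = TRUE)
  up <- qr.solve(B, (pt - 0) / 30)
  m_up <- find_mmt(make_curve(up), pt)
  expect_equal(m_up$mmp, 1L)
  expect_true(m_up$boundary)
  m_dn <- find_mmt(make_curve(-up), pt)
  expect_equal(m_dn$mmp, 99L)
  expect_true(m_dn$boundary)
})

test_that("percentile-grid argmin agrees with a 10x finer grid search", {
  spec <- demo_var_spec()
  pt <- flat_pt()
  set.seed(301)
  for (r in 1:20) {
    v0 <- runif(1, 5, 25)
    B <- eval_basis(pt, spec, clamp = TRUE)
    coef <- qr.solve(B, 0.3 * ((pt - v0) / 10)^2) + rnorm(6, sd = 0.01)
    m <- find_mmt(make_curve(coef), pt)
    fine <- stats::quantile(seq(0, 30, length.out = 1000),
                            seq(0.01, 0.99, by = 0.001), type = 7)
    vals <- drop(eval_basis(fine, spec, clamp = TRUE) %*% coef)
    fine_p <- seq(0.01, 0.99, by = 0.001)[which.min(vals)] * 100
    expect_lte(abs(m$mmp - fine_p), 1 + 1e-9)
  }
})

test_that("exposure pinned at the MMT attributes nothing", {
  d <- seq(as.Date("2012-01-01"), by = "day", length.out = 400)
  s <- daily_series("a", d, rpois(400, 10), rep(15, 400), rep(70, 400))
  set.seed(302)
  curve <- make_curve(rnorm(6, sd = 0.1))
  a <- attributable_series(s, curve, mmt = 15, max_lag = 7)
  expect_equal(a$an, rep(0, 400))
  expect_equal(sum(a$complete), 393)
})

test_that("lag-0 attribution matches the day-by-day loop oracle", {
  set.seed(303)
  d <- seq(as.Date("2012-01-01"), by = "day", length.out = 500)
  tm <- runif(500, 0, 30)
  y <- rpois(500, 12)
  s <- daily_series("a", d, y, tm, rep(70, 500))
  curve <- make_curve(rnorm(6, sd = 0.15))
  mmt <- 14
  a <- attributable_series(s, curve, mmt, max_lag = 0)
  b0 <- drop(eval_basis(mmt, curve$var_spec))
  oracle <- vapply(seq_len(500), function(t) {
    rr <- exp(drop((eval_basis(tm[t], curve$var_spec) - b0) %*% curve$coef))
    y[t] * (1 - 1 / rr)
  }, 0)
  expect_equal(sum(a$an), sum(oracle), tolerance = 1e-10)
  expect_equal(a$an, oracle, tolerance = 1e-10)
})

test_that("protective days yield negative attributable numbers", {
  d <- seq(as.Date("2012-01-01"), by = "day", length.out = 300)
  tm <- c(rep(10, 150), rep(20, 150))
  s <- daily_series("a", d, rep(10, 300), tm, rep(70, 300))
  spec <- demo_var_spec()
  # decreasing curve: cold days (10 < mmt 15) sit above zero, hot below
  B <- eval_basis(flat_pt(), spec, clamp = TRUE)
  coef <- qr.solve(B, -(flat_pt() - 15) / 30)
  a <- attributable_series(s, make_curve(coef), 15, max_lag = 0)
  expect_true(all(a$an[tm > 15] < 0))
  expect_true(all(a$an[tm < 15] > 0))
  expect_lt(sum(a$an[tm > 15]), 0)
})

test_that("mmt outside the basis domain is rejected", {
  d <- seq(as.Date("2012-01-01"), by = "day", length.out = 40)
  s <- daily_series("a", d, rep(5, 40), rep(15, 40), rep(70, 40))
  expect_error(attributable_series(s, make_curve(rep(0, 6)), 35, 0),
               "domain")
})

test_that("attribution categories partition and scale correctly", {
  set.seed(304)
  loc <- tiny_location(seed = 304, years = 2)
  s <- loc$series
  f <- fit_location(s, stage1_config())
  pt <- f$percentile_table
  mmt <- unname(pt[30])
  att <- summarize_attribution(s, f$reduced, mmt, 7, pt,
                               n_sim = 150, seed = 99)
  g <- function(cat, col = "an") att[[col]][att$category == cat]
  expect_equal(g("total"), g("cold") + g("heat"), tolerance = 1e-10)
  # every simulated draw satisfies the same partition
  sims <- attr(att, "sims")
  expect_equal(sims[, "total"], sims[, "cold"] + sims[, "heat"],
               tolerance = 1e-10)
  # percentile bands are nested subsets of their side
  expect_lte(abs(g("p1")), abs(g("p5")) + 1e-9)
  expect_lte(g("p1", "days"), g("p5", "days"))
  expect_lte(g("p99", "days"), g("p95", "days"))

  # doubling deaths doubles AN, leaves AF unchanged
  s2 <- s; s2$deaths <- 2L * s$deaths
  class(s2) <- class(s); attr(s2, "location_id") <- "x2"
  att2 <- summarize_attribution(s2, f$reduced, mmt, 7, pt,
                                n_sim = 150, seed = 99)
  expect_equal(att2$an, 2 * att$an, tolerance = 1e-10)
  expect_equal(att2$af, att$af, tolerance = 1e-10)
})

test_that("attributable fractions ignore the curve's internal centering", {
  loc <- tiny_location(seed = 305, years = 2)
  s <- loc$series
  f <- fit_location(s, stage1_config())
  pt <- f$percentile_table
  mmt <- unname(pt[40])
  a1 <- attributable_series(s, f$reduced, mmt, 7)
  # the same quantity computed through an arbitrary intermediate center:
  # eta relative to the MMT is a difference of log-RRs, so any internal
  # centering must cancel exactly
  for (c0 in unname(pt[c(10, 80)])) {
    f_day <- predict_curve(f$reduced, s$tmean, center = c0,
                           clamp = TRUE)$logrr -
      predict_curve(f$reduced, mmt, center = c0, clamp = TRUE)$logrr
    eta2 <- tempburden:::lag_window_mean(f_day, 7L)
    an2 <- s$deaths * (1 - exp(-eta2))
    an2[is.na(an2)] <- 0
    expect_equal(a1$an, an2, tolerance = 1e-10)
  }
})

test_that("empirical interval widths shrink with more draws", {
  loc <- tiny_location(seed = 306, years = 2)
  s <- loc$series
  f <- fit_location(s, stage1_config())
  pt <- f$percentile_table
  mmt <- unname(pt[25])
  expect_warning(
    summarize_attribution(s, f$reduced, mmt, 7, pt, n_sim = 50, seed = 1),
    "n_sim")
  # the empirical 95% interval stabilizes: compare spread of widths across
  # seeds at small vs large n_sim
  widths <- function(n_sim, seeds) vapply(seeds, function(sd) {
    a <- summarize_attribution(s, f$reduced, mmt, 7, pt,
                               n_sim = n_sim, seed = sd)
    a$an_high[1] - a$an_low[1]
  }, 0)
  w_small <- widths(150, 1:6)
  w_large <- widths(1200, 1:6)
  expect_lt(sd(w_large), sd(w_small))
})

test_that("aggregation sums locations and pools their draws", {
  locA <- tiny_location(seed = 307, years = 2)
  locB <- tiny_location(seed = 308, years = 2)
  parts <- lapply(list(locA, locB), function(lc) {
    f <- fit_location(lc$series, stage1_config())
    pt <- f$percentile_table
    summarize_attribution(lc$series, f$reduced, unname(pt[30]), 7, pt,
                          n_sim = 120, seed = 5)
  })
  agg <- aggregate_attribution(parts)
  expect_equal(agg$an, parts[[1]]$an + parts[[2]]$an)
  expect_equal(attr(agg, "total_deaths"),
               attr(parts[[1]], "total_deaths") +
                 attr(parts[[2]], "total_deaths"))
  expect_equal(agg$af, 100 * agg$an / attr(agg, "total_deaths"))
})
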