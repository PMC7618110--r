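# Build a meta_input directly from coefficient vectors and covariances.
raw_meta_input <- function(coefs, S, Z = NULL) {
  fits <- lapply(seq_len(nrow(coefs)), function(i)
    structure(list(coef = coefs[i, ], vcov = S[[i]],
                   var_spec = NULL, center = NULL),
              class = "reduced_curve"))
  meta_input(fits, Z)
}

test_that("identical inputs collapse to the common estimate with zero I2", {
  q <- 3
  set.seed(201)
  y <- rnorm(q)
  V <- random_psd(q, 0.05)
  inp <- raw_meta_input(matrix(rep(y, 8), 8, byrow = TRUE),
                        replicate(8, V, simplify = FALSE))
  m <- fit_meta(inp)
  expect_equal(unname(m$coef_matrix["(Intercept)", ]), y, tolerance = 1e-6)
  expect_lt(max(abs(m$Psi)), 1e-4)
  expect_equal(m$I2, 0)
})

test_that("scalar intercept-only REML matches the independent oracle", {
  skip_if_not_installed("metafor")
  set.seed(202)
  k <- 12
  vi <- runif(k, 0.02, 0.3)
  yi <- rnorm(k, 0.5, sqrt(0.1 + vi))
  inp <- raw_meta_input(matrix(yi, ncol = 1),
                        lapply(vi, function(v) matrix(v, 1, 1)))
  m <- fit_meta(inp, method = "reml")
  oracle <- metafor::rma(yi = yi, vi = vi, method = "REML",
                         control = list(tol = 1e-12))
  expect_equal(unname(m$coef_matrix[1, 1]), as.numeric(oracle$beta),
               tolerance = 1e-8)
  expect_equal(m$Psi[1, 1], oracle$tau2, tolerance = 1e-6)
  expect_equal(sqrt(m$vcov_theta[1, 1]), oracle$se, tolerance = 1e-6)
})

test_that("scalar Q and I2 match the classical formulas on five studies", {
  yi <- c(0.20, 0.35, -0.05, 0.50, 0.12)
  vi <- c(0.04, 0.09, 0.06, 0.16, 0.05)
  # classical fixed-effect Q computed by hand
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  Q_hand <- sum(w * (yi - mu_fe)^2)
  inp <- raw_meta_input(matrix(yi, ncol = 1),
                        lapply(vi, function(v) matrix(v, 1, 1)))
  m <- fit_meta(inp)
  h <- heterogeneity(m)
  expect_equal(h$Q, Q_hand, tolerance = 1e-10)
  expect_equal(h$Q_df, 4L)
  expect_equal(h$I2, max(0, (Q_hand - 4) / Q_hand) * 100, tolerance = 1e-10)
})

test_that("I2 is invariant to rescaling all outcomes by a common factor", {
  set.seed(203)
  k <- 10; q <- 2
  y <- matrix(rnorm(k * q, 0, 0.5), k)
  S <- replicate(k, random_psd(q, 0.05), simplify = FALSE)
  m1 <- fit_meta(raw_meta_input(y, S))
  m2 <- fit_meta(raw_meta_input(3 * y,
                                lapply(S, function(v) 9 * v)))
  expect_equal(m1$I2, m2$I2, tolerance = 1e-6)
  expect_equal(m1$Q, m2$Q, tolerance = 1e-8)
})

test_that("multivariate REML recovers known fixed effects and Psi", {
  set.seed(204)
  k <- 32; q <- 3; n_rep <- 30
  Psi_true <- random_psd(q, 0.04)
  z <- rnorm(k)
  B_true <- rbind(c(0.2, -0.1, 0.4), c(0.3, 0.2, -0.2))  # intercept, slope
  S <- replicate(k, random_psd(q, 0.03), simplify = FALSE)
  est_b <- matrix(NA_real_, n_rep, 2 * q)
  psi_err <- numeric(n_rep)
  Ltrue <- chol(Psi_true)
  for (r in seq_len(n_rep)) {
    y <- t(vapply(seq_len(k), function(i)
      drop(c(1, z[i]) %*% B_true) +
        drop(crossprod(Ltrue, rnorm(q))) +
        drop(crossprod(chol(S[[i]]), rnorm(q))), numeric(q)))
    m <- fit_meta(raw_meta_input(y, S, data.frame(z = z)))
    est_b[r, ] <- as.vector(m$coef_matrix)
    psi_err[r] <- norm(m$Psi - Psi_true, "F")
  }
  bias <- colMeans(est_b) - as.vector(B_true)
  mc_se <- apply(est_b, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(bias) < 4 * mc_se + 0.01))
  expect_lt(median(psi_err), 0.35 * norm(Psi_true, "F") + 0.02)
})

test_that("Wald statistic is zero for a zero coefficient and validates names", {
  set.seed(205)
  k <- 10; q <- 2
  y <- matrix(rnorm(k * q, 0, 0.3), k)
  S <- replicate(k, diag(0.05, q), simplify = FALSE)
  m <- fit_meta(raw_meta_input(y, S, data.frame(z = rnorm(k))))
  expect_error(wald_test(m, "nope"), "unknown")
  # force a zero coefficient: test the identity stat = b' V^-1 b directly
  idx <- 2 + (seq_len(q) - 1) * 2
  b <- m$theta[idx]; V <- m$vcov_theta[idx, idx]
  expect_equal(wald_test(m, "z")$stat, drop(crossprod(b, solve(V, b))),
               tolerance = 1e-10)
  expect_equal(wald_test(m, "z")$df, q)
})

test_that("inflating within-location covariances cannot raise the Wald stat", {
  set.seed(206)
  k <- 14; q <- 2
  z <- rnorm(k)
  y <- matrix(rnorm(k * q, 0, 0.3), k) + outer(z, c(0.2, -0.1))
  S <- replicate(k, random_psd(q, 0.04), simplify = FALSE)
  m1 <- fit_meta(raw_meta_input(y, S, data.frame(z = z)))
  m2 <- fit_meta(raw_meta_input(y, lapply(S, function(v) 2 * v),
                                data.frame(z = z)))
  expect_lte(wald_test(m2, "z")$stat, wald_test(m1, "z")$stat + 1e-6)
})

test_that("duplicated meta-predictors error out instead of aliasing", {
  set.seed(207)
  k <- 10
  z <- rnorm(k)
  y <- matrix(rnorm(k), ncol = 1)
  S <- replicate(k, matrix(0.05, 1, 1), simplify = FALSE)
  expect_error(fit_meta(raw_meta_input(y, S, data.frame(a = z, b = z))),
               "aliased|rank")
  expect_error(fit_meta(raw_meta_input(y, S,
                                       data.frame(a = rep(1, k)))),
               "constant")
})

test_that("REML log-likelihood at the optimum is at least its start value", {
  set.seed(208)
  k <- 12; q <- 2
  y <- matrix(rnorm(k * q, 0, 0.4), k)
  S <- replicate(k, random_psd(q, 0.05), simplify = FALSE)
  m <- fit_meta(raw_meta_input(y, S))
  expect_gte(m$loglik, m$loglik_start - 1e-8)
})

test_that("BLUPs interpolate between own estimate and pooled prediction", {
  set.seed(209)
  k <- 10; q <- 2
  y <- matrix(rnorm(k * q, 0.3, 0.4), k)
  S <- replicate(k, random_psd(q, 0.05), simplify = FALSE)
  inp <- raw_meta_input(y, S)
  m <- fit_meta(inp)
  bl <- blup(m, inp)

  # limit Psi -> 0: BLUP equals the fixed-effect prediction
  m0 <- m; m0$Psi <- matrix(0, q, q)
  bl0 <- blup(m0, inp)
  for (i in seq_len(k))
    expect_equal(bl0[[i]]$coef, unname(m$coef_matrix[1, ]),
                 ignore_attr = TRUE)

  # limit S_i -> 0: BLUP equals the location's own estimate
  inp_small <- raw_meta_input(y, replicate(k, diag(1e-10, q),
                                           simplify = FALSE))
  m_s <- fit_meta(inp_small)
  bl_s <- blup(m_s, inp_small)
  for (i in seq_len(k))
    expect_equal(bl_s[[i]]$coef, y[i, ], tolerance = 1e-4)
})

test_that("noisier locations shrink farther toward the pooled prediction", {
  set.seed(210)
  q <- 2; k <- 12
  y <- matrix(rnorm(k * q, 0.3, 0.5), k)
  S <- c(replicate(k / 2, diag(0.5, q), simplify = FALSE),   # noisy
         replicate(k / 2, diag(0.005, q), simplify = FALSE)) # precise
  inp <- raw_meta_input(y, S)
  m <- fit_meta(inp)
  bl <- blup(m, inp)
  pooled <- unname(m$coef_matrix[1, ])
  shrink <- vapply(seq_len(k), function(i) {
    own <- y[i, ]; b <- bl[[i]]$coef
    # fraction of the distance to the pooled prediction that was travelled
    sqrt(sum((b - own)^2)) / sqrt(sum((pooled - own)^2))
  }, 0)
  expect_gt(min(shrink[1:6]), max(shrink[7:12]))
})
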