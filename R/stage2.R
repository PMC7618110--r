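#' Assemble second-stage inputs
#'
#' Pairs the per-location reduced curves (outcome vectors of common length
#' `q` with their within-location covariances) with the location-level
#' meta-predictor table. Coefficients estimated on location-specific
#' percentile knots are pooled as-is: every location contributes a
#' coefficient vector of the same dimension on its own relative temperature
#' scale, following standard two-stage practice.
#'
#' @param fits list of `"stage1_fit"` objects (or of `"reduced_curve"`s).
#' @param meta_predictors data frame, one row per location, with the
#'   location-level covariates used as meta-regressors (any numeric
#'   columns; the conventional set is average temperature, temperature
#'   range, population-weighted latitude and elevation, population density,
#'   average relative humidity and a multidimensional poverty index). May
#'   be `NULL` for an intercept-only meta-analysis.
#' @return list of class `"meta_input"` with `coef` (k x q matrix), `S`
#'   (list of k covariance matrices), `Z` (k x p predictor matrix, no
#'   intercept), `location_id`.
#' @export
meta_input <- function(fits, meta_predictors = NULL) {
  curves <- lapply(fits, function(f)
    if (inherits(f, "stage1_fit")) f$reduced else f)
  stopifnot(all(vapply(curves, inherits, TRUE, "reduced_curve")))
  q <- length(curves[[1L]]$coef)
  if (!all(vapply(curves, function(cu) length(cu$coef), 1L) == q))
    stop("all locations must share the same reduced-curve dimension")
  k <- length(curves)
  ids <- vapply(seq_len(k), function(i) {
    f <- fits[[i]]
    as.character(if (inherits(f, "stage1_fit")) f$location_id else i)
  }, "")
  coef <- do.call(rbind, lapply(curves, function(cu) cu$coef))
  S <- lapply(curves, function(cu) {
    v <- (cu$vcov + t(cu$vcov)) / 2
    if (min(eigen(v, symmetric = TRUE, only.values = TRUE)$values) < -1e-8 *
        max(abs(v)))
      stop("a location covariance matrix is not positive semi-definite")
    v
  })
  Z <- NULL
  if (!is.null(meta_predictors)) {
    Z <- as.matrix(meta_predictors)
    if (!is.numeric(Z)) stop("meta-predictors must be numeric")
    if (nrow(Z) != k) stop("meta-predictor table must have one row per location")
    if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  }
  structure(list(coef = coef, S = S, Z = Z, location_id = ids),
            class = "meta_input")
}

# Build the k-list of fixed-effect design matrices X_i = I_q (x) z_i',
# outcome-major ordering: the (p+1) coefficients of outcome 1 first.
meta_design <- function(Zs, q) {
  k <- nrow(Zs)
  lapply(seq_len(k), function(i)
    kronecker(diag(q), matrix(Zs[i, ], nrow = 1L)))
}

# GLS fixed effects and REML/ML profile quantities for a given Psi.
# Returns beta (theta vector), its vcov, residuals, and -2 log-lik terms.
meta_gls <- function(y, S, Xl, Psi, reml = TRUE) {
  k <- length(S)
  q <- ncol(y)
  m <- ncol(Xl[[1L]])
  XtX <- matrix(0, m, m)
  Xty <- numeric(m)
  ldet <- 0
  Ui <- vector("list", k)
  for (i in seq_len(k)) {
    Sig <- Psi + S[[i]]
    U <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    Ui[[i]] <- U
    ldet <- ldet + 2 * sum(log(diag(U)))
    Xt <- backsolve(U, Xl[[i]], transpose = TRUE)
    yt <- backsolve(U, y[i, ], transpose = TRUE)
    XtX <- XtX + crossprod(Xt)
    Xty <- Xty + crossprod(Xt, yt)
  }
  Uxx <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(Uxx)) return(NULL)
  theta <- backsolve(Uxx, backsolve(Uxx, Xty, transpose = TRUE))
  rss <- 0
  for (i in seq_len(k)) {
    rt <- backsolve(Ui[[i]], y[i, ] - drop(Xl[[i]] %*% theta),
                    transpose = TRUE)
    rss <- rss + sum(rt^2)
  }
  n <- k * q
  ll <- -0.5 * ((n - if (reml) m else 0) * log(2 * pi) + ldet + rss +
                  if (reml) 2 * sum(log(diag(Uxx))) else 0)
  list(theta = drop(theta), vcov = chol2inv(Uxx), rss = rss, loglik = ll)
}

# Map between the lower-triangular Cholesky parameter vector (log diagonal)
# and Psi.
par_to_psi <- function(par, q) {
  Lm <- matrix(0, q, q)
  Lm[lower.tri(Lm, diag = TRUE)] <- par
  diag(Lm) <- exp(diag(Lm))
  tcrossprod(Lm)
}
psi_to_par <- function(Psi) {
  U <- chol(Psi + diag(1e-10 * max(1, mean(diag(Psi))), nrow(Psi)))
  Lm <- t(U)
  diag(Lm) <- log(diag(Lm))
  Lm[lower.tri(Lm, diag = TRUE)]
}

#' Multivariate random-effects meta-regression
#'
#' Pools per-location reduced-curve coefficients `y_i ~ N(X_i theta,
#' Psi + S_i)` across `k` locations, where `X_i` carries the location-level
#' meta-predictors (plus intercept) for each of the `q` outcome components,
#' `S_i` is the within-location covariance from stage 1 and `Psi` the
#' between-location covariance. `Psi` is estimated by restricted maximum
#' likelihood (default) or maximum likelihood over a Cholesky
#' parameterization, by quasi-Newton optimization started at
#' `Psi = 0.1 * mean(S_i)`; fixed effects are profiled out by generalized
#' least squares. Meta-predictors are standardized internally for optimizer
#' stability and effects are reported on the original scale.
#'
#' @param inputs a [meta_input()].
#' @param method `"reml"` (default) or `"ml"`.
#' @param reltol optimizer convergence tolerance.
#' @return An object of class `"meta_model"`: `theta` (fixed-effect vector,
#'   outcome-major), `coef_matrix` ((p+1) x q, rows = intercept and
#'   predictors), `vcov_theta`, `Psi`, `loglik`, `Q`, `Q_df`, `Q_p`, `I2`,
#'   `wald` (per-predictor table), plus bookkeeping fields.
#' @export
fit_meta <- function(inputs, method = c("reml", "ml"), reltol = 1e-10) {
  stopifnot(inherits(inputs, "meta_input"))
  method <- match.arg(method)
  y <- inputs$coef
  S <- inputs$S
  k <- nrow(y)
  q <- ncol(y)
  Z <- inputs$Z
  p <- if (is.null(Z)) 0L else ncol(Z)
  if (k <= p + 1L)
    stop("need more locations (", k, ") than meta-predictors plus one (",
         p + 1L, ")")

  # standardize predictors; keep the transform to back-map coefficients
  if (p > 0L) {
    ctr <- colMeans(Z)
    scl <- apply(Z, 2L, stats::sd)
    if (any(scl == 0)) stop("constant meta-predictor: ",
                            paste(colnames(Z)[scl == 0], collapse = ", "))
    Zs <- scale(Z, center = ctr, scale = scl)
    dup <- stats::cor(Zs)
    dup[upper.tri(dup, diag = TRUE)] <- 0
    if (any(abs(dup) > 1 - 1e-10)) {
      ij <- which(abs(dup) > 1 - 1e-10, arr.ind = TRUE)[1L, ]
      stop("meta-predictors are aliased (rank deficient): ",
           colnames(Z)[ij[2L]], " and ", colnames(Z)[ij[1L]])
    }
    Zd <- cbind(`(Intercept)` = 1, Zs)
  } else {
    ctr <- numeric(0); scl <- numeric(0)
    Zd <- matrix(1, k, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  Xl <- meta_design(Zd, q)
  reml <- method == "reml"

  Sbar <- Reduce(`+`, S) / k
  start <- psi_to_par(0.1 * Sbar)
  negll <- function(par) {
    g <- meta_gls(y, S, Xl, par_to_psi(par, q), reml = reml)
    if (is.null(g)) return(1e10)
    -g$loglik
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(reltol = reltol, maxit = 500L))
  if (length(start) <= 3L) {
    # low-dimensional Psi: polish to high precision with a simplex pass
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 2000L,
                                        warn.1d.NelderMead = FALSE))
    if (opt2$value <= opt$value) opt <- opt2
  }
  Psi <- par_to_psi(opt$par, q)
  g <- meta_gls(y, S, Xl, Psi, reml = reml)

  # heterogeneity at the fixed-effects-only (Psi = 0) GLS fit
  g0 <- meta_gls(y, S, Xl, matrix(0, q, q), reml = reml)
  Q <- g0$rss
  Q_df <- (k - (p + 1L)) * q
  Q_p <- stats::pchisq(Q, Q_df, lower.tail = FALSE)
  I2 <- max(0, (Q - Q_df) / Q) * 100

  # back-transform the standardized-scale coefficients to the input scale
  theta_s <- g$theta
  V_s <- g$vcov
  mstd <- p + 1L
  # per-outcome linear map std -> raw: raw_slopes = slopes/scl,
  # raw_intercept = intercept - sum(slopes * ctr / scl)
  A1 <- diag(mstd)
  if (p > 0L) {
    A1[1L, 1L + seq_len(p)] <- -ctr / scl
    for (j in seq_len(p)) A1[1L + j, 1L + j] <- 1 / scl[j]
  }
  A <- kronecker(diag(q), A1)
  theta <- drop(A %*% theta_s)
  V <- A %*% V_s %*% t(A)
  pred_names <- colnames(Zd)
  nm <- as.vector(vapply(seq_len(q), function(o)
    paste0("y", o, ":", pred_names), character(mstd)))
  names(theta) <- nm
  dimnames(V) <- list(nm, nm)
  coef_matrix <- matrix(theta, nrow = mstd, ncol = q,
                        dimnames = list(pred_names, paste0("y", seq_len(q))))

  model <- structure(
    list(theta = theta, coef_matrix = coef_matrix, vcov_theta = V,
         Psi = Psi, loglik = g$loglik, method = method,
         Q = Q, Q_df = Q_df, Q_p = Q_p, I2 = I2,
         k = k, q = q, predictors = if (p > 0L) colnames(Z) else character(0),
         center = ctr, scale = scl,
         Zd_std = Zd, converged = opt$convergence == 0L,
         loglik_start = -negll(start)),
    class = "meta_model")
  model$wald <- if (p > 0L)
    do.call(rbind, lapply(model$predictors, function(nm)
      wald_test(model, nm))) else NULL
  model
}

#' @export
print.meta_model <- function(x, ...) {
  cat(sprintf("<meta_model> %s, k = %d locations, q = %d outcomes\n",
              toupper(x$method), x$k, x$q))
  cat(sprintf("  restricted loglik %.3f | Q = %.2f on %d df (p = %.3g) | I2 = %.1f%%\n",
              x$loglik, x$Q, x$Q_df, x$Q_p, x$I2))
  if (!is.null(x$wald)) {
    cat("  Wald tests (H0: predictor does not modify the pooled curve):\n")
    print(x$wald, digits = 3)
  }
  invisible(x)
}

#' Wald test of one meta-predictor
#'
#' Tests whether a location-level covariate modifies the pooled
#' exposure-response association: `stat = b' V^-1 b` for that predictor's
#' `q` coefficients, referred to a chi-square with `q` degrees of freedom.
#'
#' @param model a [fit_meta()] result.
#' @param predictor predictor name.
#' @return one-row data frame with `predictor`, `stat`, `df`, `p`.
#' @export
wald_test <- function(model, predictor) {
  stopifnot(inherits(model, "meta_model"))
  if (!predictor %in% model$predictors)
    stop("unknown meta-predictor: ", predictor)
  mstd <- length(model$predictors) + 1L
  j <- match(predictor, model$predictors) + 1L
  idx <- j + (seq_len(model$q) - 1L) * mstd
  b <- model$theta[idx]
  V <- model$vcov_theta[idx, idx, drop = FALSE]
  stat <- drop(crossprod(b, solve(V, b)))
  data.frame(predictor = predictor, stat = stat, df = model$q,
             p = stats::pchisq(stat, model$q, lower.tail = FALSE),
             row.names = NULL)
}

#' Residual heterogeneity statistics
#'
#' Multivariate Cochran Q (residual weighted sum of squares of the
#' fixed-effects-only fit), its degrees of freedom `(k - p - 1) * q`,
#' p-value, and `I2 = max(0, (Q - df)/Q) * 100`, the share of variability
#' beyond within-location sampling error.
#'
#' @param model a [fit_meta()] result.
#' @return list with `Q`, `Q_df`, `p`, `I2`.
#' @export
heterogeneity <- function(model) {
  stopifnot(inherits(model, "meta_model"))
  list(Q = model$Q, Q_df = model$Q_df, p = model$Q_p, I2 = model$I2)
}

#' Best linear unbiased predictions of location-specific curves
#'
#' Shrinks each location's first-stage estimate toward its meta-regression
#' prediction in proportion to the relative within- and between-location
#' uncertainty: `blup_i = x_i + Psi (Psi + S_i)^-1 (y_i - x_i)` with
#' `x_i = X_i theta`. The reported covariance combines the conditional
#' variance `Psi - Psi (Psi + S_i)^-1 Psi` with the propagated uncertainty
#' of the fixed effects.
#'
#' @param model a [fit_meta()] result.
#' @param inputs the [meta_input()] the model was fitted to.
#' @param fits optional list of `"stage1_fit"` objects; when supplied, each
#'   BLUP is returned as a `"reduced_curve"` carrying that location's
#'   exposure basis, ready for prediction and attribution.
#' @return list of class `"blup_set"`: per location `coef`, `vcov`, and
#'   (when `fits` given) `curve`.
#' @export
blup <- function(model, inputs, fits = NULL) {
  stopifnot(inherits(model, "meta_model"), inherits(inputs, "meta_input"))
  k <- model$k; q <- model$q
  Xl <- meta_design(model$Zd_std, q)
  # fixed-effect uncertainty is on the standardized scale; rebuild theta there
  theta_s <- drop(solve(kron_backmap(model), model$theta))
  V_s <- solve(kron_backmap(model)) %*% model$vcov_theta %*%
    t(solve(kron_backmap(model)))
  out <- vector("list", k)
  for (i in seq_len(k)) {
    Sig <- model$Psi + inputs$S[[i]]
    W <- model$Psi %*% tryCatch(
      solve(Sig),
      error = function(e) stop(
        "Psi + S is singular for location ", inputs$location_id[i],
        "; consider a small ridge on the stage-1 covariance ",
        "(e.g. S + 1e-8 * mean(diag(S)) * I)", call. = FALSE))
    xfix <- drop(Xl[[i]] %*% theta_s)
    bl <- xfix + drop(W %*% (inputs$coef[i, ] - xfix))
    IW <- diag(q) - W
    Vb <- model$Psi - W %*% model$Psi +
      IW %*% Xl[[i]] %*% V_s %*% t(Xl[[i]]) %*% t(IW)
    Vb <- (Vb + t(Vb)) / 2
    out[[i]] <- list(location_id = inputs$location_id[i],
                     coef = bl, vcov = Vb)
    if (!is.null(fits)) {
      out[[i]]$curve <- structure(
        list(coef = bl, vcov = Vb,
             var_spec = fits[[i]]$reduced$var_spec, center = NULL),
        class = "reduced_curve")
    }
  }
  names(out) <- inputs$location_id
  structure(out, class = "blup_set")
}

# The linear map A used in fit_meta to take standardized-scale theta to the
# raw scale; its inverse recovers the standardized-scale quantities.
kron_backmap <- function(model) {
  p <- length(model$predictors)
  mstd <- p + 1L
  A1 <- diag(mstd)
  if (p > 0L) {
    A1[1L, 1L + seq_len(p)] <- -model$center / model$scale
    for (j in seq_len(p)) A1[1L + j, 1L + j] <- 1 / model$scale[j]
  }
  kronecker(diag(model$q), A1)
}
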