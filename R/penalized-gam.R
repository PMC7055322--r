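# Penalized-spline smoother: cubic B-spline basis with interior knots at
# quantiles of the predictor and a second-order difference penalty on the
# coefficients (P-spline). The smoothing weight is chosen by generalized
# cross-validation on the naive fit and then held fixed, which keeps the
# thousands of SIMEX replicate refits cheap (a 9-coefficient penalized
# least-squares solve) and prevents smoothing-level jitter from leaking
# into the extrapolation. Supported families: gaussian (identity link) and
# negative binomial (log link, dispersion estimated once on the naive fit).

ps_knots <- function(x, n_interior = 5, pad = 0.25) {
  r <- range(x)
  width <- max(r[2] - r[1], .Machine$double.eps)
  lo <- r[1] - pad * width
  hi <- r[2] + pad * width
  interior <- unname(quantile(x, probs = seq_len(n_interior) /
                                (n_interior + 1), type = 7))
  # strictly inside (lo, hi); collapse duplicates from tied x
  interior <- interior[interior > lo & interior < hi]
  c(rep(lo, 4), unique(interior), rep(hi, 4))
}

ps_basis <- function(x, knots) {
  lo <- knots[1]
  hi <- knots[length(knots)]
  splines::splineDesign(knots, pmin(pmax(x, lo), hi), ord = 4)
}

ps_penalty <- function(k) {
  d <- diff(diag(k), differences = 2)
  crossprod(d)
}

# Gaussian penalized least squares at fixed sp; returns coef and edf.
ps_solve_gaussian <- function(X, y, S, sp) {
  XtX <- crossprod(X)
  A <- XtX + sp * S
  R <- chol(A)
  beta <- backsolve(R, backsolve(R, crossprod(X, y), transpose = TRUE))
  edf <- sum(diag(backsolve(R, backsolve(R, XtX, transpose = TRUE))))
  list(coef = drop(beta), edf = edf, chol = R, XtX = XtX)
}

# Negative-binomial (log link) PIRLS at fixed sp and theta.
ps_solve_nb <- function(X, y, S, sp, theta, max_iter = 50, tol = 1e-8) {
  mu <- pmax(y, 0.1) + 0.1
  eta <- log(mu)
  dev_old <- Inf
  beta <- NULL
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + mu / theta) # mu^2 / V(mu), V = mu + mu^2/theta
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    Xw <- X * sw
    XtWX <- crossprod(Xw)
    A <- XtWX + sp * S
    R <- chol(A)
    beta <- drop(backsolve(R, backsolve(R, crossprod(Xw, z * sw),
                                        transpose = TRUE)))
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    dev <- nb_deviance(y, mu, theta)
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  edf <- sum(diag(backsolve(R, backsolve(R, XtWX, transpose = TRUE))))
  list(coef = beta, edf = edf, chol = R, XtWX = XtWX, mu = mu,
       deviance = dev)
}

nb_deviance <- function(y, mu, theta) {
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
            (y + theta) * log((y + theta) / (mu + theta)))
}

#' Fit a penalized-spline smooth of a response on one predictor
#'
#' Fits `y ~ s(x)` with a cubic B-spline basis (interior knots at quantiles
#' of `x`) and a second-order difference penalty. The smoothing weight is
#' selected by generalized cross-validation over a log-spaced grid unless
#' supplied. For the negative-binomial family (log link) the dispersion
#' parameter `theta` is estimated by maximum likelihood on the selected fit
#' unless supplied.
#'
#' @param x Numeric predictor (e.g. estimated plot profit).
#' @param y Response; non-negative integers for `negative_binomial`.
#' @param family `"gaussian"` or `"negative_binomial"`.
#' @param eval_grid Points at which to report the fitted curve; default 50
#'   equally spaced points over `range(x)`.
#' @param n_knots Number of interior knots (default 5).
#' @param sp Smoothing weight; `NULL` (default) selects it by GCV.
#' @param theta Negative-binomial dispersion; `NULL` estimates it.
#' @param knots Full knot vector (advanced); overrides `n_knots`.
#' @return An object of class `naive_fit`: coefficients, knots, `sp`,
#'   `theta`, `edf`, fitted values and pointwise standard errors on
#'   `eval_grid`, and fitted values at the data.
#' @export
#' @examples
#' x <- seq(0, 10, length.out = 32)
#' y <- rpois(32, exp(1 + 0.1 * x))
#' fit <- fit_penalized_gam(x, y, family = "negative_binomial")
#' fit$edf
fit_penalized_gam <- function(x, y,
                              family = c("gaussian", "negative_binomial"),
                              eval_grid = NULL, n_knots = 5, sp = NULL,
                              theta = NULL, knots = NULL) {
  family <- match.arg(family)
  if (length(x) != length(y)) {
    stop("domain error: x and y lengths differ", call. = FALSE)
  }
  if (length(x) < 8) {
    stop("insufficient data: need at least 8 observations", call. = FALSE)
  }
  if (family == "negative_binomial" &&
      (any(y < 0) || any(abs(y - round(y)) > 1e-8))) {
    stop("domain error: negative_binomial requires non-negative integer ",
         "responses", call. = FALSE)
  }
  if (is.null(knots)) knots <- ps_knots(x, n_interior = n_knots)
  X <- ps_basis(x, knots)
  k <- ncol(X)
  if (qr(X)$rank < 2) {
    stop("degenerate design: singular spline basis (constant predictor?)",
         call. = FALSE)
  }
  S <- ps_penalty(k)
  n <- length(y)
  sp_grid <- 10^seq(-3, 8, length.out = 45)

  if (family == "gaussian") {
    if (is.null(sp)) {
      gcv <- vapply(sp_grid, function(s) {
        f <- ps_solve_gaussian(X, y, S, s)
        rss <- sum((y - drop(X %*% f$coef))^2)
        n * rss / (n - min(f$edf, n - 0.5))^2
      }, numeric(1))
      sp <- sp_grid[which.min(gcv)]
    }
    f <- ps_solve_gaussian(X, y, S, sp)
    fitted <- drop(X %*% f$coef)
    sigma2 <- sum((y - fitted)^2) / max(n - f$edf, 1)
    # sandwich covariance of the penalized estimator
    Ainv_XtX <- backsolve(f$chol, backsolve(f$chol, f$XtX, transpose = TRUE))
    Vb <- sigma2 * backsolve(f$chol,
                             backsolve(f$chol, t(Ainv_XtX),
                                       transpose = TRUE))
    theta <- NA_real_
    dispersion <- sigma2
  } else {
    estimate_theta <- is.null(theta)
    if (estimate_theta) {
      # pilot fit at a provisional dispersion to get mu, then ML theta
      theta <- 10
      f <- ps_solve_nb(X, y, S, sp %||% 1, theta)
      theta <- nb_theta_ml(y, f$mu, theta)
    }
    if (is.null(sp)) {
      gcv <- vapply(sp_grid, function(s) {
        fs <- ps_solve_nb(X, y, S, s, theta)
        n * fs$deviance / (n - min(fs$edf, n - 0.5))^2
      }, numeric(1))
      sp <- sp_grid[which.min(gcv)]
    }
    f <- ps_solve_nb(X, y, S, sp, theta)
    if (estimate_theta) {
      theta <- nb_theta_ml(y, f$mu, theta)
      f <- ps_solve_nb(X, y, S, sp, theta)
    }
    fitted <- f$mu
    Ainv_XtWX <- backsolve(f$chol, backsolve(f$chol, f$XtWX,
                                             transpose = TRUE))
    Vb <- backsolve(f$chol, backsolve(f$chol, t(Ainv_XtWX),
                                      transpose = TRUE))
    dispersion <- 1 / theta
  }

  if (is.null(eval_grid)) eval_grid <- seq(min(x), max(x), length.out = 50)
  Xg <- ps_basis(eval_grid, knots)
  eta_g <- drop(Xg %*% f$coef)
  se_eta <- sqrt(pmax(rowSums((Xg %*% Vb) * Xg), 0))
  if (family == "gaussian") {
    fitted_grid <- eta_g
    se_grid <- se_eta
  } else {
    fitted_grid <- exp(pmin(pmax(eta_g, -30), 30))
    se_grid <- fitted_grid * se_eta # delta method on the log link
  }

  structure(
    list(family = family, knots = knots, sp = sp, theta = theta,
         coef = f$coef, edf = f$edf, dispersion = dispersion,
         eval_grid = eval_grid, fitted_grid = fitted_grid,
         se_grid = se_grid, fitted = fitted, x = x, y = y),
    class = "naive_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nb_theta_ml <- function(y, mu, theta0) {
  th <- tryCatch(
    suppressWarnings(MASS::theta.ml(y, mu, limit = 25)),
    error = function(e) theta0
  )
  min(max(as.numeric(th), 1e-3), 1e7)
}

#' @export
print.naive_fit <- function(x, ...) {
  cat(sprintf("Penalized-spline fit (%s): n = %d, edf = %.2f, sp = %.3g",
              x$family, length(x$y), x$edf, x$sp))
  if (x$family == "negative_binomial") cat(sprintf(", theta = %.3g", x$theta))
  cat("\n")
  invisible(x)
}

#' @export
predict.naive_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  eta <- drop(ps_basis(newdata, object$knots) %*% object$coef)
  if (object$family == "gaussian") eta else exp(pmin(pmax(eta, -30), 30))
}

# Fast replicate refit used inside the SIMEX loop: basis/penalty/sp/theta
# frozen from the naive fit; returns the curve on the naive eval grid.
refit_curve <- function(x, y, naive, Xg, S) {
  X <- ps_basis(x, naive$knots)
  if (naive$family == "gaussian") {
    f <- ps_solve_gaussian(X, y, S, naive$sp)
    drop(Xg %*% f$coef)
  } else {
    f <- ps_solve_nb(X, y, S, naive$sp, naive$theta, max_iter = 25)
    eta <- drop(Xg %*% f$coef)
    exp(pmin(pmax(eta, -30), 30))
  }
}
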