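# Simulation-extrapolation (SIMEX) for smooth regressions whose predictor
# (estimated plot profit) carries heteroscedastic measurement error with
# known per-observation variance sigma_e_i^2. For each inflation factor
# lambda, extra noise N(0, lambda * sigma_e_i^2) is added to the predictor
# and the smoother refitted B times; the B curves are averaged to estimate
# G(lambda), the expected fit under error variance (1 + lambda) sigma_e^2.
# A polynomial in lambda is then fitted pointwise to {(0, naive),
# (lambda_j, G(lambda_j))} and extrapolated to lambda = -1, the zero-error
# limit G(0).

#' Build a SIMEX configuration
#'
#' @param lambda_grid Positive inflation factors; default 10 equidistant
#'   values from 0.1 to 3.
#' @param B Simulation replicates per lambda (default 200).
#' @param extrapolant_degree Degree of the pointwise extrapolating
#'   polynomial, 1 (linear) or 2 (quadratic, default).
#' @param eval_grid Profit values at which curves are reported; default 50
#'   equally spaced points over the observed range.
#' @param seed Integer seed for the replicate noise.
#' @return An object of class `simex_config`.
#' @export
#' @examples
#' simex_config()$lambda_grid
simex_config <- function(lambda_grid = seq(0.1, 3, length.out = 10),
                         B = 200, extrapolant_degree = 2,
                         eval_grid = NULL, seed = 1L) {
  if (any(lambda_grid <= 0)) {
    stop("configuration error: all lambda values must be > 0", call. = FALSE)
  }
  if (B < 2) {
    stop("configuration error: B must be >= 2", call. = FALSE)
  }
  if (!extrapolant_degree %in% c(1, 2)) {
    stop("configuration error: extrapolant_degree must be 1 or 2",
         call. = FALSE)
  }
  if (!is.null(eval_grid) && any(diff(eval_grid) <= 0)) {
    stop("configuration error: eval_grid must be strictly increasing",
         call. = FALSE)
  }
  structure(
    list(lambda_grid = sort(lambda_grid), B = as.integer(B),
         extrapolant_degree = extrapolant_degree, eval_grid = eval_grid,
         seed = as.integer(seed)),
    class = "simex_config"
  )
}

#' SIMEX-correct a penalized-spline regression for measurement error
#'
#' Fits the naive smoother of `y` on the error-prone predictor `x`, then
#' performs the SIMEX simulation and extrapolation described above. The
#' spline knots, smoothing weight and (for the negative binomial) the
#' dispersion are fixed at their naive-fit values across all replicates.
#' The pointwise 95% band combines the naive fit's smoothing variance with
#' the Monte-Carlo variance of the per-lambda means propagated through the
#' extrapolant's linear weights (a delta-method construction).
#'
#' @param x Predictor values (estimated profit means).
#' @param y Response.
#' @param me_variances Per-observation measurement-error variances
#'   \eqn{\sigma_{e,i}^2 \ge 0}, aligned with `x`.
#' @param family `"gaussian"` or `"negative_binomial"`.
#' @param config A [simex_config()].
#' @param n_knots Interior knots for the spline basis (default 5).
#' @return An object of class `simex_fit`: `eval_grid`, `naive_curve`,
#'   per-lambda mean curves `G` (first row is lambda = 0, the naive curve),
#'   `corrected_curve`, `band_lo`, `band_hi`, the `naive` fit, and the
#'   configuration used.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- x + rnorm(100, 0, 0.3)
#' xw <- x + rnorm(100, 0, sqrt(0.4))
#' sf <- simex_correct(xw, y, rep(0.4, 100), "gaussian",
#'                     simex_config(B = 20, seed = 1))
#' simex_slope(sf, "corrected") > simex_slope(sf, "naive")
simex_correct <- function(x, y, me_variances,
                          family = c("gaussian", "negative_binomial"),
                          config = simex_config(), n_knots = 5) {
  family <- match.arg(family)
  stopifnot(inherits(config, "simex_config"))
  if (length(me_variances) != length(x)) {
    stop("domain error: me_variances must align with x", call. = FALSE)
  }
  if (any(me_variances < 0)) {
    stop("domain error: measurement-error variances must be >= 0",
         call. = FALSE)
  }
  lam <- config$lambda_grid
  # widen the knot span so noisy replicates stay inside the basis support
  pad_abs <- 3 * sqrt(max(lam) * max(me_variances, 0))
  width <- max(diff(range(x)), .Machine$double.eps)
  knots <- ps_knots(x, n_interior = n_knots,
                    pad = 0.25 + pad_abs / width)
  naive <- fit_penalized_gam(x, y, family = family,
                             eval_grid = config$eval_grid,
                             n_knots = n_knots, knots = knots)
  grid <- naive$eval_grid
  Xg <- ps_basis(grid, knots)
  S <- ps_penalty(ncol(Xg))
  sd_i <- sqrt(me_variances)
  n <- length(x)

  G <- matrix(NA_real_, length(lam) + 1, length(grid))
  Gvar <- matrix(0, length(lam) + 1, length(grid)) # var of the row mean
  G[1, ] <- naive$fitted_grid
  with_seed(config$seed, {
    for (l in seq_along(lam)) {
      acc <- acc2 <- numeric(length(grid))
      for (b in seq_len(config$B)) {
        xs <- x + rnorm(n) * sd_i * sqrt(lam[l])
        cv <- refit_curve(xs, y, naive, Xg, S)
        acc <- acc + cv
        acc2 <- acc2 + cv^2
      }
      m <- acc / config$B
      G[l + 1, ] <- m
      Gvar[l + 1, ] <- pmax(acc2 / config$B - m^2, 0) / config$B
    }
  })

  # pointwise polynomial extrapolation to lambda = -1
  lam_all <- c(0, lam)
  A <- outer(lam_all, 0:config$extrapolant_degree, "^")
  p_target <- (-1)^(0:config$extrapolant_degree)
  w <- drop(p_target %*% solve(crossprod(A), t(A))) # corrected = w %*% G
  corrected <- drop(w %*% G)
  var_mc <- drop(w^2 %*% Gvar)
  band_sd <- sqrt(naive$se_grid^2 + var_mc)

  structure(
    list(eval_grid = grid, naive_curve = naive$fitted_grid, lambda = lam_all,
         G = G, extrap_weights = w, corrected_curve = corrected,
         band_lo = corrected - 1.96 * band_sd,
         band_hi = corrected + 1.96 * band_sd,
         family = family, naive = naive, config = config),
    class = "simex_fit"
  )
}

#' @export
print.simex_fit <- function(x, ...) {
  cat(sprintf(
    "SIMEX-corrected smooth (%s): %d lambda values, B = %d\n  corrected curve over [%.1f, %.1f]: %.3g .. %.3g\n",
    x$family, length(x$lambda) - 1, x$config$B,
    min(x$eval_grid), max(x$eval_grid),
    x$corrected_curve[1], x$corrected_curve[length(x$corrected_curve)]
  ))
  invisible(x)
}

#' Average slope of a fitted curve over its evaluation grid
#'
#' Ordinary least-squares slope of the reported curve against the profit
#' grid; for a linear truth this is the regression slope, for a smooth it
#' summarizes the average trend. Penalized smooths are shrunk toward
#' flatness where data are sparse, so by default the summary uses only the
#' part of the grid between the `trim` and `1 - trim` quantiles of the
#' observed predictor, where the fit is supported by data.
#'
#' @param fit A `simex_fit`.
#' @param which `"corrected"` (default) or `"naive"`.
#' @param trim Quantile of the observed predictor trimmed off each end of
#'   the grid before summarizing (default 0.1; 0 uses the full grid).
#' @return A single numeric slope.
#' @export
simex_slope <- function(fit, which = c("corrected", "naive"), trim = 0.1) {
  which <- match.arg(which)
  curve <- if (which == "corrected") fit$corrected_curve else fit$naive_curve
  g <- fit$eval_grid
  if (trim > 0) {
    q <- quantile(fit$naive$x, c(trim, 1 - trim))
    keep <- g >= q[1] & g <= q[2]
    g <- g[keep]
    curve <- curve[keep]
  }
  sum((g - mean(g)) * (curve - mean(curve))) / sum((g - mean(g))^2)
}

#' Fit SIMEX-corrected response-profit curves for a dataset
#'
#' Builds the per-plot response vectors (per-taxon species richness of all
#' species, richness of forest-occurring species only, and individual
#' function indicators), then SIMEX-corrects a smooth of each response on
#' the estimated plot profits. Richness responses use the negative-binomial
#' family (counts with possible overdispersion); indicators use the
#' gaussian family. Plots without data for a group are dropped from that
#' group's fit.
#'
#' @param dataset An `eco_dataset`.
#' @param profits Plot-profit table from [predict_plot_profits()].
#' @param targets Character vector of responses, each
#'   `"richness:<group>"`, `"forest_richness:<group>"` or
#'   `"indicator:<name>"`. Default: all of them.
#' @param config A [simex_config()]; each response gets its own seed
#'   substream derived from `config$seed`.
#' @return A named list of `simex_fit` objects.
#' @export
response_profit_curves <- function(dataset, profits, targets = NULL,
                                   config = simex_config()) {
  stopifnot(inherits(dataset, "eco_dataset"))
  if (is.null(targets)) {
    targets <- c(paste0("richness:", names(dataset$incidence)),
                 paste0("forest_richness:", names(dataset$incidence)),
                 paste0("indicator:", colnames(dataset$functions)))
  }
  prof <- setNames(profits$profit_mean, profits$plot_id)
  mev <- setNames(profits$me_variance, profits$plot_id)
  out <- vector("list", length(targets))
  names(out) <- targets
  for (tg in targets) {
    parts <- strsplit(tg, ":", fixed = TRUE)[[1]]
    kind <- parts[1]
    name <- paste(parts[-1], collapse = ":")
    resp <- switch(
      kind,
      richness = {
        m <- dataset$incidence[[name]]
        if (is.null(m)) stop("lookup error: unknown group ", name,
                             call. = FALSE)
        rowSums(m)
      },
      forest_richness = {
        m <- dataset$incidence[[name]]
        if (is.null(m)) stop("lookup error: unknown group ", name,
                             call. = FALSE)
        rowSums(forest_species_subset(m, dataset$plots))
      },
      indicator = {
        if (!name %in% colnames(dataset$functions)) {
          stop("lookup error: unknown indicator ", name, call. = FALSE)
        }
        dataset$functions[, name]
      },
      stop("lookup error: unknown response kind ", kind, call. = FALSE)
    )
    keep <- !is.na(resp)
    ids <- names(resp)[keep]
    cfg <- config
    cfg$seed <- stream_seed(config$seed, paste0("simex:", tg))
    out[[tg]] <- simex_correct(
      unname(prof[ids]), unname(resp[keep]), unname(mev[ids]),
      family = if (kind == "indicator") "gaussian" else "negative_binomial",
      config = cfg
    )
  }
  out
}
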