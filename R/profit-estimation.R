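# Two-step profit estimation: per-crop OLS of household profit on yield,
# then plot-level prediction with a heteroscedastic measurement-error
# variance. The residual sd is modelled as g * yield, so it is zero at zero
# yield and forest plots (yield 0, profit fixed at 0) carry no error.

#' Fit a per-crop yield-profit regression
#'
#' Ordinary least squares of household profit on yield for one crop, with an
#' accompanying heteroscedastic residual-variance function estimated by
#' [estimate_heteroscedastic_variance()].
#'
#' @param households Household table with columns `crop`, `yield`, `profit`.
#' @param crop Crop label to fit (one of the labels in `households$crop`).
#' @return An object of class `yield_profit_fit` with elements `crop`,
#'   `intercept`, `slope`, `g` (residual-sd coefficient), `variance_fn`,
#'   `n_used`, `r_squared`, `residuals`, `yields`.
#' @export
#' @examples
#' hh <- generate_households(synth_config(seed = 1))
#' fit <- fit_yield_profit(hh, "R")
#' c(fit$intercept, fit$slope, fit$g)
fit_yield_profit <- function(households, crop) {
  d <- households[households$crop == crop &
                    is.finite(households$yield) &
                    is.finite(households$profit), , drop = FALSE]
  if (nrow(d) < 3) {
    stop("insufficient data: need at least 3 households for crop ", crop,
         call. = FALSE)
  }
  if (var(d$yield) == 0) {
    stop("degenerate design: zero yield variance for crop ", crop,
         call. = FALSE)
  }
  m <- lm(profit ~ yield, data = d)
  rss <- sum(residuals(m)^2)
  tss <- sum((d$profit - mean(d$profit))^2)
  fit <- structure(
    list(
      crop = crop,
      intercept = unname(coef(m)[1]),
      slope = unname(coef(m)[2]),
      n_used = nrow(d),
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      residuals = unname(residuals(m)),
      yields = d$yield
    ),
    class = "yield_profit_fit"
  )
  estimate_heteroscedastic_variance(fit)
}

#' Estimate the heteroscedastic residual-variance function
#'
#' Models the residual standard deviation as `g * yield` and estimates `g`
#' by regressing absolute residuals through the origin on yield; under a
#' Gaussian error assumption `E|e| = sd * sqrt(2/pi)`, so the raw
#' coefficient is rescaled by `sqrt(pi/2)`. The returned variance function
#' is `(g * yield)^2`, non-negative everywhere and exactly 0 at yield 0.
#'
#' @param fit A `yield_profit_fit` with `residuals` and `yields` attached.
#' @return The fit with elements `g` and `variance_fn` filled in.
#' @export
estimate_heteroscedastic_variance <- function(fit) {
  stopifnot(inherits(fit, "yield_profit_fit"))
  y <- fit$yields
  if (all(y == 0)) {
    stop("degenerate design: all yields zero for crop ", fit$crop,
         call. = FALSE)
  }
  g_raw <- sum(abs(fit$residuals) * y) / sum(y^2)
  fit$g <- g_raw * sqrt(pi / 2)
  g <- fit$g
  fit$variance_fn <- function(yield) (g * yield)^2
  fit
}

#' @export
print.yield_profit_fit <- function(x, ...) {
  cat(sprintf(
    "Yield-profit fit for crop %s (n = %d):\n  profit = %.3f + %.5f * yield,  sd(e) = %.5f * yield,  R^2 = %.3f\n",
    x$crop, x$n_used, x$intercept, x$slope, x$g, x$r_squared
  ))
  invisible(x)
}

#' Predict plot-level profits and measurement-error variances
#'
#' Applies the per-crop fits to the ecological plots: profit mean
#' `mu = a + b * yield` and measurement-error variance
#' `sigma_e^2 = variance_fn(yield)`. Forest plots are assigned profit 0 with
#' zero error variance.
#'
#' @param plots Plot table with columns `plot_id`, `land_use`, `yield`.
#' @param fits Named list of `yield_profit_fit` objects, or a list of fits
#'   whose `crop` elements cover every non-forest land use in `plots`.
#' @return A data frame with columns `plot_id`, `land_use`, `profit_mean`,
#'   `me_variance`.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(seed = 1))
#' fits <- fit_all_crops(ds$households)
#' head(predict_plot_profits(ds$plots, fits))
predict_plot_profits <- function(plots, fits) {
  crops <- vapply(fits, function(f) f$crop, character(1))
  names(fits) <- crops
  out <- data.frame(
    plot_id = plots$plot_id,
    land_use = plots$land_use,
    profit_mean = 0,
    me_variance = 0,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(plots))) {
    lu <- plots$land_use[i]
    if (lu == "F") next # forest: profit fixed at zero, no measurement error
    f <- fits[[lu]]
    if (is.null(f)) {
      stop("lookup error: no yield-profit fit for land use ", lu,
           call. = FALSE)
    }
    out$profit_mean[i] <- f$intercept + f$slope * plots$yield[i]
    out$me_variance[i] <- f$variance_fn(plots$yield[i])
  }
  out
}

#' Fit yield-profit regressions for every crop in a household table
#'
#' @param households Household table with columns `crop`, `yield`, `profit`.
#' @return A named list of `yield_profit_fit` objects.
#' @export
fit_all_crops <- function(households) {
  crops <- sort(unique(households$crop))
  setNames(lapply(crops, function(cr) fit_yield_profit(households, cr)),
           crops)
}
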