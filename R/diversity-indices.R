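# Threshold-based multidiversity and multifunctionality. Each group's (or
# indicator's) 100% reference is the mean of its five highest plot values;
# a plot's index at threshold t is the (weighted) proportion of groups /
# indicators reaching t times that reference. Indicators whose high values
# are undesirable are order-reversed by range reflection first.

#' Restrict an incidence matrix to species occurring in forest plots
#'
#' Keeps only the species columns with at least one presence on any forest
#' (`F`) plot; richness on the result is the "forest species" richness
#' measure.
#'
#' @param incidence Binary plot x species matrix (rows named by plot id;
#'   `NA` rows allowed for unsampled plots).
#' @param plots Plot table with `plot_id` and `land_use`.
#' @return The column-subset incidence matrix.
#' @export
#' @examples
#' inc <- rbind(Fp = c(1, 1, 0), Op = c(0, 1, 1))
#' colnames(inc) <- c("s1", "s2", "s3")
#' plots <- data.frame(plot_id = c("Fp", "Op"), land_use = c("F", "O"))
#' forest_species_subset(inc, plots)  # keeps s1, s2
forest_species_subset <- function(incidence, plots) {
  f_ids <- plots$plot_id[plots$land_use == "F"]
  f_rows <- intersect(rownames(incidence), f_ids)
  if (length(f_rows) == 0) {
    stop("precondition error: no forest plots in the dataset", call. = FALSE)
  }
  keep <- colSums(incidence[f_rows, , drop = FALSE], na.rm = TRUE) > 0
  incidence[, keep, drop = FALSE]
}

#' Maximum performance level of a group or indicator
#'
#' The 100% reference used by the threshold indices: the mean of the
#' `top_k` highest recorded plot values (all values if fewer than `top_k`),
#' which damps the influence of single outliers.
#'
#' @param values Numeric plot values (NAs ignored).
#' @param top_k How many top values to average (default 5).
#' @return The reference level.
#' @export
#' @examples
#' max_performance_level(1:10)  # mean(6:10) = 8
max_performance_level <- function(values, top_k = 5) {
  v <- values[is.finite(values)]
  if (length(v) == 0) {
    stop("domain error: no finite values to compute a performance level",
         call. = FALSE)
  }
  mean(sort(v, decreasing = TRUE)[seq_len(min(top_k, length(v)))])
}

#' Order-reversing inversion for "lower is better" indicators
#'
#' Range reflection `x' = max(x) + min(x) - x`: reverses the ordering while
#' preserving the range, is defined at zero (unlike a reciprocal), and is
#' its own inverse.
#'
#' @param values Numeric vector.
#' @return The reflected vector.
#' @export
#' @examples
#' invert_indicator(c(2, 5, 10))  # 10 7 2
invert_indicator <- function(values) {
  r <- range(values, na.rm = TRUE)
  r[2] + r[1] - values
}

#' Plot-level multidiversity at one threshold
#'
#' Proportion of the taxonomic groups measured on the plot whose species
#' richness reaches `threshold` times the group's maximum performance
#' level. Groups not sampled on the plot (`NA` richness) are excluded from
#' numerator and denominator.
#'
#' @param richness Named numeric vector: plot richness per group (`NA` =
#'   group not measured on this plot).
#' @param levels Maximum performance level per group, aligned with
#'   `richness`.
#' @param threshold Fraction in (0, 1).
#' @return A value in \[0, 1\].
#' @export
#' @examples
#' multidiversity(c(10, 5, 0), levels = c(10, 10, 10), threshold = 0.5)
multidiversity <- function(richness, levels, threshold) {
  stopifnot(length(richness) == length(levels), threshold > 0, threshold < 1)
  ok <- !is.na(richness)
  if (!any(ok)) {
    stop("domain error: no groups measured on this plot", call. = FALSE)
  }
  mean(richness[ok] >= threshold * levels[ok])
}

#' Plot-level multifunctionality at one threshold
#'
#' Weighted proportion of (direction-corrected) indicators reaching
#' `threshold` times their maximum performance level, with each indicator
#' weighted by `1 / (number of indicators of its function)` so that every
#' function contributes equally; the sum is divided by the number of
#' functions, giving a value in \[0, 1\].
#'
#' @param values Direction-corrected indicator values for one plot, aligned
#'   with `meta`.
#' @param meta Data frame with columns `indicator` and `fn_group` (and
#'   optionally `weight`, which must sum to 1 within each function).
#' @param levels Maximum performance levels per indicator (computed on
#'   direction-corrected values).
#' @param threshold Fraction in (0, 1).
#' @return A value in \[0, 1\].
#' @export
multifunctionality <- function(values, meta, levels, threshold) {
  stopifnot(length(values) == nrow(meta), length(levels) == nrow(meta),
            threshold > 0, threshold < 1)
  if (is.null(meta$weight)) {
    meta$weight <- 1 / ave(rep(1, nrow(meta)), meta$fn_group, FUN = sum)
  } else {
    sums <- tapply(meta$weight, meta$fn_group, sum)
    if (any(abs(sums - 1) > 1e-8)) {
      stop("metadata error: indicator weights must sum to 1 within each ",
           "function group", call. = FALSE)
    }
  }
  ok <- !is.na(values)
  if (!any(ok)) {
    stop("domain error: no indicators measured on this plot", call. = FALSE)
  }
  pass <- values[ok] >= threshold * levels[ok]
  sum(meta$weight[ok] * pass) / length(unique(meta$fn_group[ok]))
}

#' Build a threshold configuration
#'
#' @param thresholds Strictly increasing fractions in \[0.01, 0.99\];
#'   default the 99 one-percentage-point steps.
#' @param top_k Top values averaged for the maximum performance level.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(thresholds = seq(0.01, 0.99, by = 0.01),
                             top_k = 5) {
  if (any(thresholds < 0.01 - 1e-12) || any(thresholds > 0.99 + 1e-12) ||
      any(diff(thresholds) <= 0)) {
    stop("configuration error: thresholds must be strictly increasing ",
         "within [0.01, 0.99]", call. = FALSE)
  }
  structure(list(thresholds = thresholds, top_k = as.integer(top_k)),
            class = "threshold_config")
}

#' Compute an index across the full threshold range
#'
#' Computes multidiversity (from the per-group richness of the incidence
#' matrices) or multifunctionality (from the direction-corrected function
#' indicators) for every plot at every configured threshold.
#'
#' @param dataset An `eco_dataset`.
#' @param kind `"multidiversity"` or `"multifunctionality"`.
#' @param config A [threshold_config()].
#' @return A numeric matrix plots x thresholds of class `index_table` with
#'   attributes `kind` and `thresholds`.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(seed = 1))
#' md <- threshold_sweep(ds, "multidiversity",
#'                       threshold_config(seq(0.1, 0.9, 0.1)))
#' dim(md)
threshold_sweep <- function(dataset, kind = c("multidiversity",
                                              "multifunctionality"),
                            config = threshold_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "eco_dataset"),
            inherits(config, "threshold_config"))
  thr <- config$thresholds
  ids <- dataset$plots$plot_id
  out <- matrix(NA_real_, length(ids), length(thr),
                dimnames = list(ids, sprintf("t%02d", round(100 * thr))))
  if (kind == "multidiversity") {
    rich <- vapply(dataset$incidence,
                   function(m) rowSums(m)[ids], numeric(length(ids)))
    levels <- apply(rich, 2, max_performance_level, top_k = config$top_k)
    for (j in seq_along(thr)) {
      out[, j] <- apply(rich, 1, multidiversity, levels = levels,
                        threshold = thr[j])
    }
  } else {
    vals <- dataset$functions[ids, , drop = FALSE]
    meta <- dataset$functions_meta
    low <- meta$direction == "lower_better"
    vals[, low] <- apply(vals[, low, drop = FALSE], 2, invert_indicator)
    # a proportional threshold needs a ratio scale: indicators measured on
    # scales reaching below zero (e.g. net CH4 flux) are shifted to a zero
    # minimum after direction correction
    vals <- apply(vals, 2, function(v) {
      mn <- min(v, na.rm = TRUE)
      if (mn < 0) v - mn else v
    })
    levels <- apply(vals, 2, max_performance_level, top_k = config$top_k)
    for (j in seq_along(thr)) {
      out[, j] <- apply(vals, 1, multifunctionality, meta = meta,
                        levels = levels, threshold = thr[j])
    }
  }
  structure(out, kind = kind, thresholds = thr, class = "index_table")
}

#' Regress an index on profit across thresholds
#'
#' For every threshold column, fits a simple linear regression of the index
#' on the plot profit means and reports the slope per 100 USD
#' ha\eqn{^{-1}} yr\eqn{^{-1}} with a 95% confidence interval.
#'
#' @param index_table An `index_table` from [threshold_sweep()].
#' @param profits Plot-profit table from [predict_plot_profits()] (or any
#'   data frame with `plot_id` and `profit_mean`).
#' @return A data frame with columns `threshold`, `slope_per_100usd`,
#'   `lo`, `hi`.
#' @export
index_profit_slope <- function(index_table, profits) {
  stopifnot(inherits(index_table, "index_table"))
  prof <- setNames(profits$profit_mean, profits$plot_id)[
    rownames(index_table)]
  if (length(prof) < 3) {
    stop("insufficient data: need at least 3 plots", call. = FALSE)
  }
  if (isTRUE(all.equal(var(prof), 0))) {
    stop("degenerate design: constant profits", call. = FALSE)
  }
  thr <- attr(index_table, "thresholds")
  res <- data.frame(threshold = thr, slope_per_100usd = NA_real_,
                    lo = NA_real_, hi = NA_real_)
  for (j in seq_along(thr)) {
    m <- lm(index_table[, j] ~ prof)
    res$slope_per_100usd[j] <- 100 * coef(m)[2]
    ci <- suppressWarnings(confint(m, "prof", level = 0.95))
    res$lo[j] <- 100 * ci[1]
    res$hi[j] <- 100 * ci[2]
  }
  res
}
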