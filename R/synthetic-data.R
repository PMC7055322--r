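#' Generate plot records
#'
#' Creates the plot table of the emulated design: for each landscape block
#' and land-use system, `n_replicates` plots. Yields for the cropped systems
#' are drawn from the configured normal distributions and truncated at zero;
#' forest plots have yield exactly 0.
#'
#' @param config A [synth_config()] object.
#' @return A data frame with columns `plot_id`, `land_use`, `landscape`,
#'   `yield` (kg ha\eqn{^{-1}} yr\eqn{^{-1}}).
#' @export
#' @examples
#' plots <- generate_plots(synth_config(seed = 42))
#' table(plots$land_use)
generate_plots <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- expand.grid(
    rep = seq_len(config$n_replicates),
    land_use = config$systems,
    landscape = paste0("L", seq_len(config$n_landscapes)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  plots <- data.frame(
    plot_id = sprintf("%s_%s%d", grid$landscape, grid$land_use, grid$rep),
    land_use = grid$land_use,
    landscape = grid$landscape,
    yield = 0,
    stringsAsFactors = FALSE
  )
  with_seed(stream_seed(config$seed, "plots"), {
    for (i in seq_len(nrow(config$yields))) {
      crop <- config$yields$crop[i]
      sel <- plots$land_use == crop
      plots$yield[sel] <- pmax(
        0,
        rnorm(sum(sel), config$yields$mean[i], config$yields$sd[i])
      )
    }
  })
  plots$yield[plots$land_use == "F"] <- 0
  plots
}

#' Generate species incidence matrices
#'
#' For each taxonomic group, draws a binary plot x species matrix with the
#' configured turnover structure: the species pool is split into a forest
#' pool and a non-forest pool; forest plots sample only the forest pool,
#' while converted plots draw a fraction `forest_overlap` of their expected
#' richness from the forest pool and the rest from the non-forest pool.
#' Each species is included independently with the land-use-specific
#' probability, so expected plot richness equals the configured mean.
#' Species never observed anywhere are dropped. Groups with `n_missing > 0`
#' get that many plots set to `NA` (unsampled), chosen in a seeded stream.
#'
#' @param plots Plot table from [generate_plots()].
#' @param config A [synth_config()] object.
#' @return A named list of integer matrices (rows = plots, 0/1 entries, `NA`
#'   rows for unsampled plots), one per taxonomic group.
#' @export
generate_species_incidence <- function(plots, config) {
  stopifnot(inherits(config, "synth_config"))
  taxa <- config$taxa
  if (nrow(taxa) == 0) {
    stop("configuration error: taxa spec is empty", call. = FALSE)
  }
  out <- vector("list", nrow(taxa))
  names(out) <- taxa$group
  for (g in seq_len(nrow(taxa))) {
    out[[g]] <- with_seed(
      stream_seed(config$seed, paste0("incidence:", taxa$group[g])),
      incidence_one_group(plots, taxa[g, ], config$systems)
    )
  }
  out
}

incidence_one_group <- function(plots, tx, systems) {
  pool <- tx$pool
  pool_f <- ceiling(pool / 2) # forest-pool size
  pool_n <- pool - pool_f
  means <- setNames(
    unlist(tx[paste0("mean_", c("F", "J", "R", "O"))]),
    c("F", "J", "R", "O")
  )
  omega <- tx$forest_overlap
  # per-species inclusion probabilities per land use, split across pools
  p_f <- p_n <- setNames(numeric(4), names(means))
  for (lu in names(means)) {
    m <- means[[lu]]
    if (lu == "F") {
      pf <- m / pool_f
      pn <- 0
    } else {
      pf <- if (pool_f > 0) omega * m / pool_f else 0
      pn <- if (pool_n > 0) (1 - omega) * m / pool_n else (1 - omega) * m
    }
    if (pf > 1 || pn > 1 || (pool_n == 0 && (1 - omega) * m > 0)) {
      stop(sprintf(
        "configuration error: mean richness %.1f for land use %s exceeds the %s pool of group %s",
        m, lu, if (pf > 1) "forest" else "non-forest", tx$group
      ), call. = FALSE)
    }
    p_f[lu] <- pf
    p_n[lu] <- pn
  }
  n_plots <- nrow(plots)
  mat <- matrix(0L, n_plots, pool,
                dimnames = list(plots$plot_id, sprintf("%s_sp%03d", tx$group,
                                                       seq_len(pool))))
  for (i in seq_len(n_plots)) {
    lu <- plots$land_use[i]
    probs <- c(rep(p_f[[lu]], pool_f), rep(p_n[[lu]], pool_n))
    mat[i, ] <- as.integer(runif(pool) < probs)
  }
  if (tx$n_missing > 0) {
    miss <- sample(n_plots, tx$n_missing)
    mat[miss, ] <- NA_integer_
  }
  seen <- colSums(mat, na.rm = TRUE) > 0
  mat[, seen, drop = FALSE]
}

#' Generate ecosystem-function indicator values
#'
#' Indicator value = configured land-use mean + Gaussian noise with the
#' configured standard deviation. Direction flags travel in the metadata
#' table; no inversion happens here.
#'
#' @param plots Plot table from [generate_plots()].
#' @param config A [synth_config()] object.
#' @return A list with `values` (numeric matrix plots x indicators) and
#'   `meta` (data frame `indicator`, `fn_group`, `direction`).
#' @export
generate_function_indicators <- function(plots, config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$functions
  vals <- matrix(NA_real_, nrow(plots), nrow(fs),
                 dimnames = list(plots$plot_id, fs$indicator))
  with_seed(stream_seed(config$seed, "functions"), {
    for (j in seq_len(nrow(fs))) {
      mu <- setNames(
        unlist(fs[j, paste0("mean_", c("F", "J", "R", "O"))]),
        c("F", "J", "R", "O")
      )
      vals[, j] <- mu[plots$land_use] + rnorm(nrow(plots), 0, fs$sd[j])
    }
  })
  list(
    values = vals,
    meta = data.frame(
      indicator = fs$indicator,
      fn_group = fs$fn_group,
      direction = fs$direction,
      stringsAsFactors = FALSE
    )
  )
}

#' Generate the household yield-profit survey
#'
#' For each crop, draws household yields from the plot-level yield
#' distribution (truncated at zero) and profits from the linear relation
#' `profit = a + b * yield + e` with heteroscedastic residual standard
#' deviation `sd(e) = gamma * yield`, so the residual spread grows with
#' yield and vanishes at zero yield.
#'
#' @param config A [synth_config()] object.
#' @return A data frame with columns `household_id`, `crop`, `yield`,
#'   `profit` (USD ha\eqn{^{-1}} yr\eqn{^{-1}}).
#' @export
generate_households <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  hh <- config$households
  with_seed(stream_seed(config$seed, "households"), {
    rows <- lapply(seq_len(nrow(hh)), function(i) {
      n <- hh$n[i]
      ys <- config$yields[config$yields$crop == hh$crop[i], ]
      if (nrow(ys) != 1) {
        stop("configuration error: no yield spec for crop ", hh$crop[i],
             call. = FALSE)
      }
      y <- pmax(0, rnorm(n, ys$mean, ys$sd))
      profit <- hh$intercept[i] + hh$slope[i] * y +
        rnorm(n, 0, hh$gamma[i] * y)
      data.frame(crop = hh$crop[i], yield = y, profit = profit,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out <- cbind(household_id = sprintf("hh%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic dataset
#'
#' Runs all four generators under one root seed and bundles the results.
#'
#' @param config A [synth_config()] object.
#' @return An object of class `eco_dataset`: a list with elements `plots`,
#'   `incidence`, `functions`, `functions_meta`, `households`, `config`.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(seed = 42))
#' ds
generate_dataset <- function(config = synth_config()) {
  plots <- generate_plots(config)
  fi <- generate_function_indicators(plots, config)
  structure(
    list(
      plots = plots,
      incidence = generate_species_incidence(plots, config),
      functions = fi$values,
      functions_meta = fi$meta,
      households = generate_households(config),
      config = config
    ),
    class = "eco_dataset"
  )
}

#' @export
print.eco_dataset <- function(x, ...) {
  cat("Plot-based trade-off dataset\n")
  cat(sprintf("  plots:      %d (%s)\n", nrow(x$plots),
              paste(sprintf("%s:%d", names(table(x$plots$land_use)),
                            table(x$plots$land_use)), collapse = " ")))
  cat(sprintf("  taxa:       %d groups, %d species in total\n",
              length(x$incidence),
              sum(vapply(x$incidence, ncol, integer(1)))))
  cat(sprintf("  functions:  %d indicators in %d groups\n",
              ncol(x$functions), length(unique(x$functions_meta$fn_group))))
  cat(sprintf("  households: %d\n",
              if (is.null(x$households)) 0L else nrow(x$households)))
  invisible(x)
}

#' Write a dataset to CSV files
#'
#' Writes `plots.csv`, one `incidence_<group>.csv` per taxonomic group,
#' `functions.csv`, `functions_meta.csv` and `households.csv` into a
#' directory, in the schema read back by [load_dataset()].
#'
#' @param dataset An `eco_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eco_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- dataset$plots
  names(p)[names(p) == "yield"] <- "yield_kg_ha_yr"
  paths["plots"] <- file.path(dir, "plots.csv")
  write.csv(p, paths["plots"], row.names = FALSE)
  for (g in names(dataset$incidence)) {
    f <- file.path(dir, paste0("incidence_", g, ".csv"))
    write.csv(data.frame(plot_id = rownames(dataset$incidence[[g]]),
                         dataset$incidence[[g]], check.names = FALSE),
              f, row.names = FALSE)
    paths[paste0("incidence_", g)] <- f
  }
  paths["functions"] <- file.path(dir, "functions.csv")
  write.csv(data.frame(plot_id = rownames(dataset$functions),
                       dataset$functions, check.names = FALSE),
            paths["functions"], row.names = FALSE)
  paths["functions_meta"] <- file.path(dir, "functions_meta.csv")
  write.csv(dataset$functions_meta, paths["functions_meta"],
            row.names = FALSE)
  if (!is.null(dataset$households)) {
    h <- dataset$households
    names(h)[names(h) == "profit"] <- "profit_usd_ha_yr"
    paths["households"] <- file.path(dir, "households.csv")
    write.csv(h, paths["households"], row.names = FALSE)
  }
  invisible(paths)
}
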