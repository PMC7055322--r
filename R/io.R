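# Dataset loading with located validation errors, plus end-to-end pipeline
# orchestration writing a reproducible manifest.

#' Load and validate a dataset directory
#'
#' Reads the CSV schema written by [write_dataset()] (`plots.csv`,
#' `incidence_<group>.csv`, `functions.csv`, `functions_meta.csv`, optional
#' `households.csv`) and cross-checks it: incidence entries binary, plot
#' ids consistent across tables, direction flags valid. Violations raise an
#' error naming file, column and row.
#'
#' @param dir Directory containing the CSV files.
#' @return A validated `eco_dataset` (with `config = NULL`).
#' @export
#' @examples
#' dir <- tempfile()
#' write_dataset(generate_dataset(synth_config(seed = 1)), dir)
#' ds <- load_dataset(dir)
load_dataset <- function(dir) {
  read_file <- function(name, required = TRUE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) {
        stop("validation error: missing file ", name, " in ", dir,
             call. = FALSE)
      }
      return(NULL)
    }
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  need_cols <- function(d, name, cols) {
    miss <- setdiff(cols, names(d))
    if (length(miss)) {
      stop("validation error: file ", name, " lacks column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }

  plots <- read_file("plots.csv")
  need_cols(plots, "plots.csv",
            c("plot_id", "land_use", "landscape", "yield_kg_ha_yr"))
  names(plots)[names(plots) == "yield_kg_ha_yr"] <- "yield"
  bad <- which(!is.finite(plots$yield) | plots$yield < 0)
  if (length(bad)) {
    stop("validation error: plots.csv, column yield_kg_ha_yr, row ", bad[1],
         ": yields must be finite and >= 0", call. = FALSE)
  }
  bad <- which(plots$land_use == "F" & plots$yield != 0)
  if (length(bad)) {
    stop("validation error: plots.csv, row ", bad[1],
         ": forest plots must have yield 0", call. = FALSE)
  }

  inc_files <- list.files(dir, pattern = "^incidence_.*\\.csv$")
  incidence <- list()
  for (f in inc_files) {
    d <- read_file(f)
    need_cols(d, f, "plot_id")
    m <- as.matrix(d[, setdiff(names(d), "plot_id"), drop = FALSE])
    rownames(m) <- d$plot_id
    bad <- which(!(is.na(m) | m == 0 | m == 1), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("validation error: ", f, ", column ",
           colnames(m)[bad[1, 2]], ", row ", bad[1, 1],
           ": incidence entries must be 0 or 1", call. = FALSE)
    }
    extra <- setdiff(rownames(m), plots$plot_id)
    if (length(extra)) {
      stop("validation error: ", f, ": plot ", extra[1],
           " absent from plots.csv", call. = FALSE)
    }
    group <- sub("^incidence_(.*)\\.csv$", "\\1", f)
    incidence[[group]] <- m[plots$plot_id, , drop = FALSE]
    storage.mode(incidence[[group]]) <- "integer"
  }

  fn <- read_file("functions.csv")
  need_cols(fn, "functions.csv", "plot_id")
  fmat <- as.matrix(fn[, setdiff(names(fn), "plot_id"), drop = FALSE])
  rownames(fmat) <- fn$plot_id
  extra <- setdiff(rownames(fmat), plots$plot_id)
  if (length(extra)) {
    stop("validation error: functions.csv: plot ", extra[1],
         " absent from plots.csv", call. = FALSE)
  }
  fmat <- fmat[plots$plot_id, , drop = FALSE]

  meta <- read_file("functions_meta.csv")
  need_cols(meta, "functions_meta.csv",
            c("indicator", "fn_group", "direction"))
  bad <- which(!meta$direction %in% c("higher_better", "lower_better"))
  if (length(bad)) {
    stop("validation error: functions_meta.csv, column direction, row ",
         bad[1], ": must be higher_better or lower_better", call. = FALSE)
  }
  miss <- setdiff(colnames(fmat), meta$indicator)
  if (length(miss)) {
    stop("validation error: functions.csv column ", miss[1],
         " has no functions_meta.csv entry", call. = FALSE)
  }

  hh <- read_file("households.csv", required = FALSE)
  if (!is.null(hh)) {
    need_cols(hh, "households.csv",
              c("household_id", "crop", "yield", "profit_usd_ha_yr"))
    names(hh)[names(hh) == "profit_usd_ha_yr"] <- "profit"
    bad <- which(!is.finite(hh$yield) | hh$yield < 0)
    if (length(bad)) {
      stop("validation error: households.csv, column yield, row ", bad[1],
           ": yields must be finite and >= 0", call. = FALSE)
    }
  }

  structure(
    list(plots = plots, incidence = incidence, functions = fmat,
         functions_meta = meta[, c("indicator", "fn_group", "direction")],
         households = hh, config = NULL),
    class = "eco_dataset"
  )
}

#' Build a pipeline run configuration
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param seed Root seed; every stage derives its own substream.
#' @param stages Which stages to run, in dependency order; subset of
#'   `c("simulate", "profits", "simex", "indices", "optimize")`. Stages
#'   other than `simulate` require either `simulate` in `stages` or
#'   `data_dir` pointing at an existing dataset.
#' @param data_dir Directory with an existing dataset (used when
#'   `simulate` is not run).
#' @param synth A [synth_config()] for the simulate stage.
#' @param simex A [simex_config()] for the smoother stage.
#' @param simex_targets Responses for the simex stage (default: richness of
#'   every taxonomic group); see [response_profit_curves()].
#' @param thresholds A [threshold_config()] for the index stage.
#' @param ga A [ga_config()] for the optimization stage.
#' @param objective An [objective_spec()] for the optimization stage.
#' @param expectations Profit-expectation grid for the optimization stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "profits", "simex", "indices",
                                  "optimize"),
                       data_dir = NULL,
                       synth = NULL, simex = NULL, simex_targets = NULL,
                       thresholds = threshold_config(),
                       ga = ga_config(),
                       objective = objective_spec("multidiversity"),
                       expectations = seq(0, 1000, by = 200)) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!"simulate" %in% stages && is.null(data_dir)) {
    stop("dependency error: stages beyond 'simulate' need data_dir when ",
         "simulate is disabled", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         data_dir = data_dir,
         synth = synth %||% synth_config(seed = stream_seed(seed, "synth")),
         simex = simex %||%
           simex_config(seed = stream_seed(seed, "simex")),
         simex_targets = simex_targets,
         thresholds = thresholds,
         ga = local({
           g <- ga
           g$seed <- stream_seed(seed, "ga")
           g
         }),
         objective = objective, expectations = expectations),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate, profits,
#' simex, indices, optimize — writing each stage's artifacts to
#' `config$out_dir` and a `manifest.json` listing inputs, outputs and
#' seeds. Re-running with the same configuration and seed reproduces the
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   package_version =
                     as.character(utils::packageVersion("ecoprofit")))

  dataset <- NULL
  profits <- NULL
  data_dir <- config$data_dir

  if ("simulate" %in% config$stages) {
    dataset <- generate_dataset(config$synth)
    data_dir <- file.path(config$out_dir, "data")
    files <- write_dataset(dataset, data_dir)
    manifest$stages$simulate <- list(
      seed = config$synth$seed, outputs = unname(files)
    )
  }
  need_data <- function() {
    if (is.null(dataset)) {
      if (is.null(data_dir)) {
        stop("dependency error: no dataset available; enable 'simulate' ",
             "or set data_dir", call. = FALSE)
      }
      dataset <<- load_dataset(data_dir)
    }
    dataset
  }
  need_profits <- function() {
    if (is.null(profits)) {
      ds <- need_data()
      if (is.null(ds$households)) {
        stop("dependency error: profits stage requires household data",
             call. = FALSE)
      }
      fits <- fit_all_crops(ds$households)
      profits <<- predict_plot_profits(ds$plots, fits)
      f <- file.path(config$out_dir, "plot_profits.csv")
      write.csv(profits[, c("plot_id", "profit_mean", "me_variance")], f,
                row.names = FALSE)
      fj <- file.path(config$out_dir, "fits.json")
      jsonlite::write_json(
        lapply(fits, function(x) {
          list(crop = x$crop, a = x$intercept, b = x$slope, g = x$g,
               n = x$n_used, r_squared = x$r_squared)
        }),
        fj, auto_unbox = TRUE, digits = NA
      )
      manifest$stages$profits <<- list(outputs = c(f, fj))
    }
    profits
  }

  if ("profits" %in% config$stages) need_profits()

  if ("simex" %in% config$stages) {
    ds <- need_data()
    pr <- need_profits()
    targets <- config$simex_targets %||%
      paste0("richness:", names(ds$incidence))
    curves <- response_profit_curves(ds, pr, targets, config$simex)
    f <- file.path(config$out_dir, "simex_curves.json")
    jsonlite::write_json(
      lapply(curves, function(s) {
        list(family = s$family, lambda_grid = s$lambda[-1],
             B = s$config$B, eval_grid = s$eval_grid,
             naive_curve = s$naive_curve,
             corrected_curve = s$corrected_curve,
             band_lo = s$band_lo, band_hi = s$band_hi,
             seed = s$config$seed)
      }),
      f, digits = NA, auto_unbox = TRUE
    )
    manifest$stages$simex <- list(targets = targets, outputs = f,
                                  seed = config$simex$seed)
  }

  if ("indices" %in% config$stages) {
    ds <- need_data()
    pr <- need_profits()
    outs <- character(0)
    for (kind in c("multidiversity", "multifunctionality")) {
      idx <- threshold_sweep(ds, kind, config$thresholds)
      f <- file.path(config$out_dir, paste0(kind, ".csv"))
      write.csv(data.frame(plot_id = rownames(idx), unclass(idx),
                           check.names = FALSE), f, row.names = FALSE)
      slopes <- index_profit_slope(idx, pr)
      fs <- file.path(config$out_dir, paste0(kind, "_slopes.csv"))
      write.csv(slopes, fs, row.names = FALSE)
      outs <- c(outs, f, fs)
    }
    manifest$stages$indices <- list(outputs = outs)
  }

  if ("optimize" %in% config$stages) {
    ds <- need_data()
    pr <- need_profits()
    ps <- pareto_frontier(config$objective, config$expectations, ds, pr,
                          config$ga)
    f <- file.path(config$out_dir, "solutions.json")
    jsonlite::write_json(
      lapply(ps$solutions, function(s) {
        list(status = s$status, expectation = s$expectation,
             realized = s$realized, mean_profit = s$mean_profit,
             shares = as.list(s$shares),
             plot_counts = as.list(s$plot_counts))
      }),
      f, digits = NA, auto_unbox = TRUE
    )
    ff <- file.path(config$out_dir, "frontier.csv")
    write.csv(ps$frontier, ff, row.names = FALSE)
    manifest$stages$optimize <- list(outputs = c(f, ff),
                                     seed = config$ga$seed)
  }

  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
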