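# Shared fixtures: all built in code, nothing read from disk.

# Wrap raw components into the dataset container.
toy_dataset <- function(plots, incidence = list(), functions = NULL,
                        meta = NULL) {
  structure(
    list(plots = plots, incidence = incidence, functions = functions,
         functions_meta = meta, households = NULL, config = NULL),
    class = "eco_dataset"
  )
}

toy_profits <- function(plots, profit_mean, me_variance = 0) {
  data.frame(plot_id = plots$plot_id, land_use = plots$land_use,
             profit_mean = profit_mean,
             me_variance = rep_len(me_variance, nrow(plots)))
}

# Six-plot toy instance for optimizer tests: profits span 0..1000 and the
# species sets overlap so that union richness is a non-trivial objective.
toy6 <- function(seed = 1) {
  plots <- data.frame(
    plot_id = paste0("p", 1:6),
    land_use = c("F", "F", "J", "R", "O", "O"),
    landscape = "L1",
    yield = c(0, 0, 500, 900, 15000, 20000)
  )
  set.seed(seed)
  inc <- matrix(rbinom(6 * 15, 1, 0.4), 6, 15,
                dimnames = list(plots$plot_id, paste0("s", 1:15)))
  inc <- inc[, colSums(inc) > 0, drop = FALSE]
  storage.mode(inc) <- "integer"
  list(
    dataset = toy_dataset(plots, list(bugs = inc)),
    profits = toy_profits(plots, c(0, 0, 200, 450, 800, 1000))
  )
}

# Default synthetic dataset cached per test run (generation is cheap but
# used by many tests).
default_ds <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) cache <<- generate_dataset(synth_config(seed = seed))
    cache
  }
})

default_profits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- default_ds()
      cache <<- predict_plot_profits(ds$plots, fit_all_crops(ds$households))
    }
    cache
  }
})
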