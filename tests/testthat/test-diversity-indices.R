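test_that("forest species subsetting keeps exactly the forest-present species", {
  inc <- rbind(f1 = c(1L, 1L, 0L), o1 = c(0L, 1L, 1L))
  colnames(inc) <- c("s1", "s2", "s3")
  plots <- data.frame(plot_id = c("f1", "o1"), land_use = c("F", "O"))
  sub <- forest_species_subset(inc, plots)
  expect_equal(colnames(sub), c("s1", "s2"))
  expect_equal(unname(rowSums(sub)["o1"]), 1)

  # all species forest-present: identity
  inc2 <- rbind(f1 = c(1L, 1L), o1 = c(1L, 0L))
  colnames(inc2) <- c("a", "b")
  expect_identical(forest_species_subset(inc2, plots), inc2)

  # no forest plots
  plots$land_use <- c("O", "O")
  expect_error(forest_species_subset(inc, plots), "precondition error")
})

test_that("maximum performance level averages the top values", {
  expect_equal(max_performance_level(1:10), 8)
  expect_equal(max_performance_level(c(2, 4, 6)), 4)
  expect_equal(max_performance_level(rep(7, 20)), 7)
  expect_equal(max_performance_level(c(NA, 5)), 5)
  expect_error(max_performance_level(NA_real_), "domain error")
})

test_that("indicator inversion is an order-reversing involution", {
  expect_equal(invert_indicator(c(2, 5, 10)), c(10, 7, 2))
  expect_equal(invert_indicator(rep(3, 5)), rep(3, 5))
  for (s in 1:10) {
    set.seed(s)
    v <- rnorm(20)
    expect_equal(invert_indicator(invert_indicator(v)), v)
    expect_equal(order(invert_indicator(v)), rev(order(v)))
    expect_equal(range(invert_indicator(v)), range(v))
  }
})

test_that("multidiversity counts threshold attainment over measured groups", {
  expect_equal(multidiversity(c(10, 5, 0), rep(10, 3), 0.5), 2 / 3)
  expect_equal(multidiversity(c(1, 2, 3), rep(10, 3), 0.99), 0)
  # missing group: denominator adjusts
  r <- c(rep(10, 13), NA)
  expect_equal(multidiversity(r, rep(10, 14), 0.5), 1)
  expect_error(multidiversity(rep(NA_real_, 3), rep(1, 3), 0.5),
               "domain error")
})

test_that("multifunctionality weights indicators so functions count equally", {
  meta <- data.frame(indicator = c("a1", "a2", "b1"),
                     fn_group = c("A", "A", "B"))
  levels <- c(10, 10, 10)
  # a1 passes, a2 fails, b1 passes at threshold 0.5
  expect_equal(multifunctionality(c(10, 2, 10), meta, levels, 0.5), 0.75)
  expect_equal(multifunctionality(c(10, 10, 10), meta, levels, 0.5), 1)
  # an 8-indicator function: each pass adds 1/8 of that function's share
  meta8 <- data.frame(indicator = paste0("x", 1:8), fn_group = "X")
  vals <- c(rep(10, 3), rep(0, 5))
  expect_equal(multifunctionality(vals, meta8, rep(10, 8), 0.5), 3 / 8)
  # explicit weights must sum to 1 within a function
  meta$weight <- c(0.6, 0.6, 1)
  expect_error(multifunctionality(c(1, 1, 1), meta, levels, 0.5),
               "metadata error")
})

test_that("splitting an indicator into identical copies leaves the index unchanged", {
  meta <- data.frame(indicator = c("a1", "b1"), fn_group = c("A", "B"))
  v <- c(8, 3)
  lev <- c(10, 10)
  base <- multifunctionality(v, meta, lev, 0.5)
  meta2 <- data.frame(indicator = c("a1", "a1b", "b1"),
                      fn_group = c("A", "A", "B"))
  expect_equal(
    multifunctionality(c(8, 8, 3), meta2, c(10, 10, 10), 0.5), base
  )
})

test_that("threshold sweeps stay in [0,1] and decrease with the threshold", {
  ds <- default_ds()
  cfg <- threshold_config()
  expect_length(cfg$thresholds, 99)
  for (kind in c("multidiversity", "multifunctionality")) {
    idx <- threshold_sweep(ds, kind, cfg)
    expect_equal(dim(idx), c(32, 99))
    expect_true(all(idx >= 0 & idx <= 1))
    expect_true(all(apply(idx, 1, function(r) all(diff(r) <= 1e-12))))
  }
  expect_error(threshold_config(c(0.5, 0.2)), "configuration error")
  expect_error(threshold_config(c(0.001, 0.5)), "configuration error")
})

test_that("index-profit slopes are exact on linear data", {
  plots <- data.frame(plot_id = paste0("p", 1:8), land_use = "R")
  prof <- toy_profits(plots, seq(0, 700, by = 100))
  idx <- structure(
    matrix(1 - 0.0008 * prof$profit_mean, 8, 1,
           dimnames = list(plots$plot_id, "t50")),
    thresholds = 0.5, kind = "multidiversity", class = "index_table"
  )
  sl <- index_profit_slope(idx, prof)
  expect_equal(sl$slope_per_100usd, -0.08)
  expect_equal(sl$hi - sl$lo, 0, tolerance = 1e-8)

  # constant index: slope 0
  idx[] <- 0.5
  expect_equal(index_profit_slope(idx, prof)$slope_per_100usd, 0)

  # constant profits: degenerate
  prof$profit_mean <- 5
  expect_error(index_profit_slope(idx, prof), "degenerate design")
})

test_that("synthetic richness declines give negative mid-threshold slopes", {
  ds <- default_ds()
  pr <- default_profits()
  idx <- threshold_sweep(ds, "multidiversity",
                         threshold_config(seq(0.3, 0.7, by = 0.1)))
  sl <- index_profit_slope(idx, pr)
  expect_true(all(sl$slope_per_100usd < 0))
  expect_true(all(sl$lo <= sl$slope_per_100usd &
                    sl$slope_per_100usd <= sl$hi))
})
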