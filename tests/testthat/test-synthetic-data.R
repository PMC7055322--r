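test_that("plot generation honours the replicated block design", {
  cfg <- synth_config(seed = 42)
  plots <- generate_plots(cfg)
  expect_equal(nrow(plots), 32)
  expect_true(all(table(plots$land_use) == 8))
  expect_true(all(table(plots$landscape) == 16))
  expect_true(all(plots$yield[plots$land_use == "F"] == 0))
  expect_true(all(plots$yield >= 0))
})

test_that("degenerate yield noise gives identical yields", {
  ys <- default_yield_spec()
  ys$sd[ys$crop == "O"] <- 0
  plots <- generate_plots(synth_config(yields = ys, seed = 7))
  o <- plots$yield[plots$land_use == "O"]
  expect_true(all(o == ys$mean[ys$crop == "O"]))
})

test_that("generation is deterministic given the seed and streams are stable", {
  a <- generate_dataset(synth_config(seed = 5))
  b <- generate_dataset(synth_config(seed = 5))
  expect_identical(a$plots, b$plots)
  expect_identical(a$incidence, b$incidence)
  expect_identical(a$functions, b$functions)
  expect_identical(a$households, b$households)
  # a different root seed changes the data
  c <- generate_dataset(synth_config(seed = 6))
  expect_false(identical(a$plots$yield, c$plots$yield))
})

test_that("incidence matrices are binary with per-land-use mean richness", {
  taxa <- data.frame(group = "g", pool = 200, mean_F = 60, mean_J = 40,
                     mean_R = 20, mean_O = 10, forest_overlap = 0.5,
                     n_missing = 0L)
  cfg <- synth_config(taxa = taxa, seed = 1)
  plots <- generate_plots(cfg)
  # Monte-Carlo: mean realized richness per land use within 10% of target
  sums <- setNames(numeric(4), c("F", "J", "R", "O"))
  n_sims <- 200
  for (s in seq_len(n_sims)) {
    cfg$seed <- s
    m <- generate_species_incidence(plots, cfg)[["g"]]
    expect_true(all(m %in% c(0L, 1L)))
    rich <- rowSums(m)
    sums <- sums + tapply(rich, plots$land_use, mean)[names(sums)]
  }
  got <- as.numeric(sums / n_sims)
  expect_equal(got, c(60, 40, 20, 10), tolerance = 0.1)
})

test_that("full forest overlap confines converted-plot species to the forest pool", {
  taxa <- data.frame(group = "g", pool = 100, mean_F = 30, mean_J = 20,
                     mean_R = 15, mean_O = 10, forest_overlap = 1,
                     n_missing = 0L)
  cfg <- synth_config(taxa = taxa, seed = 3)
  plots <- generate_plots(cfg)
  m <- generate_species_incidence(plots, cfg)[["g"]]
  # forest pool = first ceiling(pool/2) species of the group
  pool_f <- paste0("g_sp", sprintf("%03d", 1:50))
  mono <- plots$plot_id[plots$land_use %in% c("R", "O")]
  present <- colnames(m)[colSums(m[mono, , drop = FALSE]) > 0]
  expect_true(all(present %in% pool_f))
})

test_that("zero richness yields an empty group, and infeasible means error", {
  taxa <- data.frame(group = "g", pool = 50, mean_F = 0, mean_J = 0,
                     mean_R = 0, mean_O = 0, forest_overlap = 0.5,
                     n_missing = 0L)
  cfg <- synth_config(taxa = taxa, seed = 1)
  plots <- generate_plots(cfg)
  m <- generate_species_incidence(plots, cfg)[["g"]]
  expect_equal(ncol(m), 0)
  expect_equal(unname(rowSums(m)), rep(0, 32))

  taxa$mean_F <- 40 # exceeds the 25-species forest pool
  cfg2 <- synth_config(taxa = taxa, seed = 1)
  expect_error(generate_species_incidence(plots, cfg2),
               "configuration error")
})

test_that("groups with unsampled plots carry NA rows", {
  ds <- default_ds()
  n_na <- vapply(ds$incidence,
                 function(m) sum(is.na(rowSums(m))), integer(1))
  expect_equal(unname(n_na[c("archaea", "fungi")]), c(2L, 2L))
  expect_equal(unname(n_na[c("birds", "testate_amoebae")]), c(1L, 1L))
})

test_that("function indicators follow land-use means with configured noise", {
  fs <- default_function_spec()
  expect_equal(nrow(fs), 36)
  expect_equal(length(unique(fs$fn_group)), 10)
  fs$sd <- 0
  cfg <- synth_config(functions = fs, seed = 9)
  plots <- generate_plots(cfg)
  fi <- generate_function_indicators(plots, cfg)
  expect_equal(ncol(fi$values), 36)
  for (j in c(1, 17, 36)) {
    mu <- setNames(unlist(fs[j, paste0("mean_", c("F", "J", "R", "O"))]),
                   c("F", "J", "R", "O"))
    expect_equal(unname(fi$values[, j]), unname(mu[plots$land_use]))
  }
})

test_that("household profits are linear in yield with sd growing in yield", {
  cfg <- synth_config(seed = 11)
  hh <- generate_households(cfg)
  expect_equal(nrow(hh), 701)

  # gamma = 0: profits exactly on the line
  spec0 <- default_household_spec()
  spec0$gamma <- 0
  hh0 <- generate_households(synth_config(households = spec0, seed = 2))
  for (cr in c("J", "R", "O")) {
    d <- hh0[hh0$crop == cr, ]
    s <- spec0[spec0$crop == cr, ]
    expect_equal(d$profit, s$intercept + s$slope * d$yield)
  }

  # gamma > 0: residual spread larger in the top yield quartile
  big <- default_household_spec()
  big$n <- c(234L, 233L, 233L) # ~700 households
  hhb <- generate_households(synth_config(households = big, seed = 4))
  for (cr in c("J", "R")) {
    d <- hhb[hhb$crop == cr, ]
    s <- big[big$crop == cr, ]
    res <- d$profit - (s$intercept + s$slope * d$yield)
    qs <- quantile(d$yield, c(0.25, 0.75))
    expect_gt(sd(res[d$yield >= qs[2]]), sd(res[d$yield <= qs[1]]))
  }
})

test_that("OLS on generated households recovers the configured line", {
  spec <- default_household_spec()
  for (s in 1:5) {
    hh <- generate_households(synth_config(households = spec, seed = s))
    for (cr in c("J", "R", "O")) {
      d <- hh[hh$crop == cr, ]
      m <- lm(profit ~ yield, d)
      se <- coef(summary(m))[, "Std. Error"]
      tr <- spec[spec$crop == cr, ]
      expect_lt(abs(coef(m)[1] - tr$intercept), 3 * se[1])
      expect_lt(abs(coef(m)[2] - tr$slope), 3 * se[2])
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(systems = c("F", "J", "R")),
               "configuration error")
  expect_error(synth_config(n_landscapes = 0), "configuration error")
  bad <- default_household_spec()
  bad$gamma[1] <- -0.1
  expect_error(synth_config(households = bad), "configuration error")
  taxa <- default_taxa_spec()
  taxa$forest_overlap[1] <- 1.2
  expect_error(synth_config(taxa = taxa), "configuration error")
  fs <- default_function_spec()
  fs$direction[1] <- "sideways"
  expect_error(synth_config(functions = fs), "configuration error")
})
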