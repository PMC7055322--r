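test_that("search-space size is the exact multiset count", {
  expect_equal(as.numeric(search_space_size(2, 2)), 3)
  expect_equal(as.numeric(search_space_size(1, 7)), 7)
  big <- search_space_size(32, 32)
  expect_identical(attr(big, "exact"), "916312070471295267")
  # agreement with explicit enumeration counts for small instances
  count_multisets <- function(n, L) {
    cnt <- 0
    rec <- function(pos, start) {
      if (pos > L) {
        cnt <<- cnt + 1
        return(invisible())
      }
      for (i in start:n) rec(pos + 1, i)
    }
    rec(1, 1)
    cnt
  }
  for (n in 1:5) {
    for (L in 1:5) {
      expect_equal(as.numeric(search_space_size(L, n)),
                   count_multisets(n, L))
    }
  }
})

test_that("chromosome decoding maps gene g to plot g mod n_plots", {
  ch <- integer(1024)
  ch[c(1, 34)] <- 1L # genes 0 and 33 -> plots 1 and 2
  counts <- decode_chromosome(ch, 32)
  expect_equal(counts[1:2], c(1L, 1L))
  expect_equal(sum(counts), 2)
  expect_equal(decode_chromosome(rep(1L, 1024), 32), rep(32L, 32))
  expect_equal(decode_chromosome(integer(1024), 32), rep(0L, 32))
  expect_error(decode_chromosome(integer(1000), 32), "encoding error")
})

test_that("mean profit is the multiplicity-weighted average", {
  expect_equal(mean_profit(c(32), 600), 600)
  expect_equal(mean_profit(c(16, 16), c(0, 1000)), 500)
  expect_error(mean_profit(c(0, 0), c(1, 2)), "domain error")
  expect_error(mean_profit(c(1, 1), 1), "lookup error")
})

test_that("union richness objective ignores duplicate plots", {
  plots <- data.frame(plot_id = c("A", "B"), land_use = c("F", "O"),
                      landscape = "L1", yield = c(0, 100))
  inc <- rbind(A = c(1L, 1L, 0L), B = c(0L, 1L, 1L))
  colnames(inc) <- paste0("s", 1:3)
  ds <- toy_dataset(plots, list(g = inc))
  pr <- toy_profits(plots, c(0, 100))
  spec <- objective_spec("group_richness", "g")
  expect_equal(landscape_objective(c(1, 1), spec, ds, pr), 1)
  expect_equal(landscape_objective(c(2, 0), spec, ds, pr), 2 / 3)
  expect_error(landscape_objective(c(1, 1),
                                   objective_spec("group_richness", "nope"),
                                   ds, pr),
               "lookup error")
})

test_that("function level averages standardized slot values", {
  plots <- data.frame(plot_id = c("A", "B", "C"), land_use = c("F", "J", "O"),
                      landscape = "L1", yield = 0:2)
  fn <- matrix(c(10, 5, 0), 3, 1, dimnames = list(plots$plot_id, "ind"))
  meta <- data.frame(indicator = "ind", fn_group = "fx",
                     direction = "higher_better")
  ds <- toy_dataset(plots, functions = fn, meta = meta)
  pr <- toy_profits(plots, c(0, 1, 2))
  spec <- objective_spec("function_level", "fx")
  # standardized slot values 1.0 and 0.5 over L = 2 slots
  expect_equal(landscape_objective(c(1, 1, 0), spec, ds, pr), 0.75)
  expect_equal(landscape_objective(c(3, 0, 0), spec, ds, pr), 1)
})

test_that("two-plot instance is solved exactly by GA and oracle", {
  plots <- data.frame(plot_id = c("P1", "P2"), land_use = c("F", "O"),
                      landscape = "L1", yield = c(0, 100))
  inc <- rbind(P1 = c(rep(1L, 10), rep(0L, 2)),
               P2 = c(rep(0L, 10), rep(1L, 2)))
  colnames(inc) <- paste0("s", 1:12)
  ds <- toy_dataset(plots, list(g = inc))
  pr <- toy_profits(plots, c(0, 1000))
  spec <- objective_spec("group_richness", "g")
  bf <- brute_force_optimize(spec, 500, ds, pr, L = 2)
  expect_equal(unname(bf$plot_counts), c(1, 1))
  expect_equal(bf$realized, 1)
  expect_equal(bf$mean_profit, 500)
  ga <- run_ga(spec, 500, ds, pr, ga_config(50, 25, seed = 1), L = 2)
  expect_equal(ga$realized, bf$realized)
  expect_equal(unname(ga$plot_counts), unname(bf$plot_counts))
})

test_that("brute force refuses over-budget instances and flags infeasibility", {
  toy <- toy6()
  spec <- objective_spec("group_richness", "bugs")
  expect_error(
    brute_force_optimize(spec, 0, toy$dataset, toy$profits, L = 6,
                         budget = 100),
    "enumeration refused"
  )
  sol <- brute_force_optimize(spec, 5000, toy$dataset, toy$profits, L = 4)
  expect_identical(sol$status, "no_solution")
  expect_false(sol$feasible)
  ga <- run_ga(spec, 5000, toy$dataset, toy$profits,
               ga_config(20, 5, seed = 1), L = 4)
  expect_identical(ga$status, "no_solution")
})

test_that("GA attains the enumeration optimum on small instances", {
  spec <- objective_spec("group_richness", "bugs")
  for (s in 1:5) {
    toy <- toy6(seed = s)
    for (e in c(0, 500)) {
      bf <- brute_force_optimize(spec, e, toy$dataset, toy$profits, L = 4)
      ga <- run_ga(spec, e, toy$dataset, toy$profits,
                   ga_config(100, 50, seed = s), L = 4)
      expect_equal(ga$realized, bf$realized, tolerance = 1e-12)
      expect_gte(ga$mean_profit, e)
    }
  }
})

test_that("GA runs are deterministic given the seed", {
  toy <- toy6()
  spec <- objective_spec("group_richness", "bugs")
  a <- run_ga(spec, 300, toy$dataset, toy$profits,
              ga_config(50, 20, seed = 7), L = 4)
  b <- run_ga(spec, 300, toy$dataset, toy$profits,
              ga_config(50, 20, seed = 7), L = 4)
  expect_identical(a$plot_counts, b$plot_counts)
  expect_identical(a$realized, b$realized)
})

test_that("adding a plot never decreases union richness", {
  toy <- toy6(seed = 3)
  spec <- objective_spec("group_richness", "bugs")
  for (s in 1:20) {
    set.seed(s)
    counts <- tabulate(sample(6, 4, replace = TRUE), 6)
    base <- landscape_objective(counts, spec, toy$dataset, toy$profits)
    add <- counts
    add[sample(6, 1)] <- add[sample(6, 1)] + 1
    expect_gte(landscape_objective(add, spec, toy$dataset, toy$profits),
               base - 1e-12)
  }
})

test_that("landscape size adapts to groups with unsampled plots", {
  ds <- default_ds()
  pr <- default_profits()
  sol <- run_ga(objective_spec("group_richness", "archaea"), 0, ds, pr,
                ga_config(20, 3, seed = 1))
  expect_equal(sol$L, 30)
  expect_equal(sum(sol$plot_counts), 30)
  expect_equal(sum(sol$shares), 1)
})

test_that("pareto frontier is monotone with unit share sums", {
  toy <- toy6()
  spec <- objective_spec("group_richness", "bugs")
  ps <- pareto_frontier(spec, c(0, 200, 400, 600, 800, 1000),
                        toy$dataset, toy$profits,
                        ga_config(60, 25, seed = 2), L = 4)
  fr <- ps$frontier
  ok <- fr$feasible
  expect_true(all(diff(fr$realized[ok]) <= 1e-9))
  for (s in ps$solutions) {
    if (s$status == "ok") expect_equal(sum(s$shares), 1)
  }
  # exact-oracle cross-check after monotonicity repair
  for (i in which(ok)) {
    bf <- brute_force_optimize(spec, fr$expectation[i], toy$dataset,
                               toy$profits, L = 4)
    expect_lte(fr$realized[i], bf$realized + 1e-9)
  }
})
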