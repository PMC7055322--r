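# Profit-constrained optimization of conceptual landscape composition: L
# slots (default 32, one per study plot) filled with replacement from the
# study plots, maximizing an ecological objective subject to a minimum
# multiplicity-weighted mean profit. The encoding follows the binary scheme
# of the original analysis: each plot's inclusion is a gene replicated L
# times, giving an L * n_plots chromosome (1024 genes for 32 plots); gene g
# maps to plot (g mod n_plots).

#' Build an objective specification
#'
#' @param kind `"group_richness"` (union richness of a taxonomic group
#'   across the distinct included plots), `"function_level"` (mean of
#'   min-max standardized, direction-corrected indicator values of one
#'   function over all slots), `"multidiversity"` or `"multifunctionality"`
#'   (multiplicity-weighted mean plot-level index at `threshold`).
#' @param target Taxonomic group or function name (ignored for the
#'   multi-indices).
#' @param threshold Index threshold for the multi-indices (default 0.5).
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(kind = c("group_richness", "function_level",
                                    "multidiversity", "multifunctionality"),
                           target = NULL, threshold = 0.5) {
  kind <- match.arg(kind)
  if (kind %in% c("group_richness", "function_level") && is.null(target)) {
    stop("lookup error: kind '", kind, "' requires a target name",
         call. = FALSE)
  }
  structure(list(kind = kind, target = target, threshold = threshold),
            class = "objective_spec")
}

#' Build a genetic-algorithm configuration
#'
#' @param population_size Chromosomes per generation (default 500).
#' @param generations Number of generations (default 100).
#' @param mutation_rate Per-bit flip probability; default
#'   `1 / (chromosome length + 1)`.
#' @param elitism_fraction Fraction of the population carried over
#'   unchanged (default 0.2).
#' @param seed Integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 500, generations = 100,
                      mutation_rate = NULL, elitism_fraction = 0.2,
                      seed = 1L) {
  if (population_size < 2) {
    stop("configuration error: population_size must be >= 2", call. = FALSE)
  }
  if (generations < 1) {
    stop("configuration error: generations must be >= 1", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         mutation_rate = mutation_rate,
         elitism_fraction = elitism_fraction, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Decode a binary chromosome into a plot multiset
#'
#' Gene `g` (0-based) maps to plot `g mod n_plots`; each set gene adds one
#' copy of its plot.
#'
#' @param chromosome Binary vector of length `n_plots^2` (or any multiple
#'   of `n_plots`).
#' @param n_plots Number of distinct plots.
#' @return Integer vector of per-plot copy counts (length `n_plots`).
#' @export
#' @examples
#' ch <- integer(1024); ch[c(1, 34)] <- 1L  # genes 0 and 33
#' which(decode_chromosome(ch, 32) > 0)     # plots 1 and 2
decode_chromosome <- function(chromosome, n_plots) {
  if (length(chromosome) %% n_plots != 0) {
    stop("encoding error: chromosome length must be a multiple of n_plots",
         call. = FALSE)
  }
  set <- which(chromosome != 0)
  tabulate((set - 1L) %% n_plots + 1L, n_plots)
}

# Gene-to-plot map as a sparse-ish indicator matrix for vectorized decoding
# of a whole population: counts = bits %*% gene_map.
gene_map <- function(len, n_plots) {
  m <- matrix(0, len, n_plots)
  m[cbind(seq_len(len), (seq_len(len) - 1L) %% n_plots + 1L)] <- 1
  m
}

# Precompute everything the fitness function needs for one objective.
prepare_objective <- function(dataset, profits, spec) {
  stopifnot(inherits(dataset, "eco_dataset"),
            inherits(spec, "objective_spec"))
  ids <- dataset$plots$plot_id
  mu <- setNames(profits$profit_mean, profits$plot_id)[ids]

  if (spec$kind == "group_richness") {
    inc <- dataset$incidence[[spec$target]]
    if (is.null(inc)) {
      stop("lookup error: unknown taxonomic group ", spec$target,
           call. = FALSE)
    }
    avail <- ids[!is.na(rowSums(inc[ids, , drop = FALSE]))]
    inc <- inc[avail, , drop = FALSE]
    total <- ncol(inc)
    value <- function(counts_mat) {
      present <- (counts_mat > 0) %*% inc
      rowSums(present > 0) / total
    }
  } else if (spec$kind == "function_level") {
    meta <- dataset$functions_meta
    cols <- meta$indicator[meta$fn_group == spec$target]
    if (length(cols) == 0) {
      stop("lookup error: unknown function ", spec$target, call. = FALSE)
    }
    vals <- dataset$functions[ids, cols, drop = FALSE]
    low <- meta$direction[match(cols, meta$indicator)] == "lower_better"
    vals[, low] <- apply(vals[, low, drop = FALSE], 2, invert_indicator)
    std <- apply(vals, 2, function(v) {
      r <- range(v, na.rm = TRUE)
      if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(1, length(v))
    })
    score <- rowMeans(std) # per-slot contribution in [0, 1]
    avail <- ids[!is.na(score)]
    score <- score[match(avail, ids)]
    value <- function(counts_mat) {
      drop(counts_mat %*% score) / rowSums(counts_mat)
    }
  } else {
    idx <- threshold_sweep(dataset, spec$kind,
                           threshold_config(spec$threshold))
    score <- idx[ids, 1]
    avail <- ids[!is.na(score)]
    score <- score[match(avail, ids)]
    value <- function(counts_mat) {
      drop(counts_mat %*% score) / rowSums(counts_mat)
    }
  }

  list(
    ids = avail,
    n_plots = length(avail),
    land_use = dataset$plots$land_use[match(avail, ids)],
    systems = unique(dataset$plots$land_use),
    mu = unname(mu[avail]),
    value = value
  )
}

#' Realized ecological objective of a landscape multiset
#'
#' @param counts Integer vector of per-plot copy counts, aligned with the
#'   plots available for the objective (in `dataset$plots` order).
#' @param spec An [objective_spec()].
#' @param dataset An `eco_dataset`.
#' @param profits Plot-profit table from [predict_plot_profits()].
#' @return Realized objective in \[0, 1\].
#' @export
landscape_objective <- function(counts, spec, dataset, profits) {
  obj <- prepare_objective(dataset, profits, spec)
  if (length(counts) != obj$n_plots) {
    stop("encoding error: counts length must equal the number of ",
         "available plots (", obj$n_plots, ")", call. = FALSE)
  }
  drop(obj$value(matrix(counts, 1)))
}

#' Multiplicity-weighted mean profit of a landscape multiset
#'
#' @param counts Integer per-plot copy counts.
#' @param plot_profits Profit means aligned with `counts` (numeric vector),
#'   or a plot-profit table whose rows align.
#' @return Mean profit in USD ha\eqn{^{-1}} yr\eqn{^{-1}}.
#' @export
#' @examples
#' mean_profit(c(16, 16), c(0, 1000))  # 500
mean_profit <- function(counts, plot_profits) {
  mu <- if (is.data.frame(plot_profits)) plot_profits$profit_mean
        else plot_profits
  if (length(counts) != length(mu)) {
    stop("lookup error: counts and profits are not aligned", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("domain error: empty landscape multiset", call. = FALSE)
  }
  sum(counts * mu) / sum(counts)
}

# Constraint-dominance fitness: feasible solutions score their realized
# objective (in [0, 1]); infeasible ones score a negative value that shrinks
# with the profit shortfall, so any feasible solution outranks any
# infeasible one while the GA is still guided toward feasibility.
ga_fitness_values <- function(counts_mat, obj, expectation) {
  realized <- obj$value(counts_mat)
  profit <- drop(counts_mat %*% obj$mu) / rowSums(counts_mat)
  feasible <- profit >= expectation - 1e-9
  shortfall <- pmax(expectation - profit, 0) / (abs(expectation) + 1)
  fit <- ifelse(feasible, realized, -0.001 - shortfall)
  list(fitness = fit, realized = realized, profit = profit,
       feasible = feasible)
}

repair_bits <- function(bits, L) {
  s <- sum(bits)
  if (s > L) {
    on <- which(bits == 1L)
    bits[on[sample.int(s, s - L)]] <- 0L
  } else if (s < L) {
    off <- which(bits == 0L)
    bits[off[sample.int(length(off), L - s)]] <- 1L
  }
  bits
}

make_solution <- function(counts, obj, realized, profit, expectation,
                          feasible) {
  L <- sum(counts)
  shares <- vapply(
    obj$systems,
    function(lu) sum(counts[obj$land_use == lu]) / L,
    numeric(1)
  )
  names(shares) <- obj$systems
  structure(
    list(plot_counts = setNames(counts, obj$ids), L = L,
         realized = realized, mean_profit = profit,
         shares = shares, expectation = expectation,
         feasible = feasible, status = "ok"),
    class = "landscape_solution"
  )
}

no_solution <- function(expectation) {
  structure(
    list(plot_counts = NULL, L = NA_integer_, realized = NA_real_,
         mean_profit = NA_real_, shares = NULL, expectation = expectation,
         feasible = FALSE, status = "no_solution"),
    class = "landscape_solution"
  )
}

#' @export
print.landscape_solution <- function(x, ...) {
  if (x$status == "no_solution") {
    cat(sprintf("No feasible landscape at expectation %.0f USD/ha/yr\n",
                x$expectation))
    return(invisible(x))
  }
  cat(sprintf(
    "Landscape solution (L = %d, expectation %.0f USD/ha/yr):\n  realized = %.3f, mean profit = %.1f\n  shares: %s\n",
    x$L, x$expectation, x$realized, x$mean_profit,
    paste(sprintf("%s %.2f", names(x$shares), x$shares), collapse = ", ")
  ))
  invisible(x)
}

#' Optimize landscape composition with a binary genetic algorithm
#'
#' Maximizes the ecological objective over landscapes of `L` slots filled
#' with replacement from the available plots, subject to a minimum mean
#' profit. Chromosomes are repaired to exactly `L` set genes before
#' evaluation; selection is rank-proportional with elitism, crossover is
#' single-point, mutation is bit-flip. Deterministic given
#' `config$seed`.
#'
#' @param spec An [objective_spec()].
#' @param expectation Minimum mean profit (USD ha\eqn{^{-1}} yr\eqn{^{-1}})
#'   a landscape must reach to be feasible.
#' @param dataset An `eco_dataset`.
#' @param profits Plot-profit table from [predict_plot_profits()].
#' @param config A [ga_config()].
#' @param L Landscape size; default the number of plots with data for the
#'   objective (32, or fewer for groups with unsampled plots).
#' @return A `landscape_solution`; `status == "no_solution"` if no feasible
#'   landscape was found.
#' @export
run_ga <- function(spec, expectation, dataset, profits,
                   config = ga_config(), L = NULL) {
  obj <- prepare_objective(dataset, profits, spec)
  n <- obj$n_plots
  if (is.null(L)) L <- n
  if (L < 1 || L > n * n) {
    stop("configuration error: landscape size L out of range", call. = FALSE)
  }
  len <- n * n
  mrate <- config$mutation_rate %||% (1 / (len + 1))
  gm <- gene_map(len, n)
  pop_n <- config$population_size
  n_elite <- max(1L, floor(config$elitism_fraction * pop_n))

  with_seed(config$seed, {
    pop <- matrix(as.integer(runif(pop_n * len) < L / len), pop_n, len)
    for (i in seq_len(pop_n)) pop[i, ] <- repair_bits(pop[i, ], L)

    best <- NULL
    for (gen in seq_len(config$generations)) {
      counts <- pop %*% gm
      ev <- ga_fitness_values(counts, obj, expectation)
      top <- which.max(ev$fitness)
      if (ev$feasible[top] &&
          (is.null(best) || ev$realized[top] > best$realized + 1e-12)) {
        best <- list(counts = counts[top, ], realized = ev$realized[top],
                     profit = ev$profit[top])
      }
      if (gen == config$generations) break

      ord <- order(ev$fitness, decreasing = TRUE)
      elite <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      n_off <- pop_n - n_elite
      # rank-proportional selection
      pr <- (pop_n - rank(-ev$fitness, ties.method = "first") + 1)
      pr <- pr / sum(pr)
      p1 <- sample.int(pop_n, n_off, replace = TRUE, prob = pr)
      p2 <- sample.int(pop_n, n_off, replace = TRUE, prob = pr)
      cut <- sample.int(len - 1L, n_off, replace = TRUE)
      child <- pop[p1, , drop = FALSE]
      other <- pop[p2, , drop = FALSE]
      take <- col(child) > cut # single-point crossover tail from parent 2
      child[take] <- other[take]
      flip <- matrix(runif(n_off * len) < mrate, n_off, len)
      child[flip] <- 1L - child[flip]
      for (i in seq_len(n_off)) child[i, ] <- repair_bits(child[i, ], L)
      pop <- rbind(elite, child)
    }
  })

  if (is.null(best)) return(no_solution(expectation))
  make_solution(best$counts, obj, best$realized, best$profit, expectation,
                TRUE)
}

#' Exact landscape optimum by full multiset enumeration
#'
#' Enumerates every multiset of `L` slots over the available plots and
#' returns the best feasible solution; the small-instance oracle used to
#' validate the genetic algorithm. Ties are broken toward the
#' lexicographically smallest multiset.
#'
#' @inheritParams run_ga
#' @param budget Maximum number of candidates to enumerate (default 1e6);
#'   larger instances are refused with a size report.
#' @return A `landscape_solution`.
#' @export
brute_force_optimize <- function(spec, expectation, dataset, profits,
                                 L = NULL, budget = 1e6) {
  obj <- prepare_objective(dataset, profits, spec)
  n <- obj$n_plots
  if (is.null(L)) L <- n
  size <- search_space_size(L, n)
  if (size > budget) {
    stop(sprintf(
      "enumeration refused: search space has %s candidates (budget %g)",
      attr(size, "exact"), budget
    ), call. = FALSE)
  }
  best <- NULL
  idx <- integer(L)
  rec <- function(pos, start) {
    if (pos > L) {
      counts <- tabulate(idx, n)
      realized <- drop(obj$value(matrix(counts, 1)))
      profit <- sum(counts * obj$mu) / L
      if (profit >= expectation - 1e-9) {
        if (is.null(best) || realized > best$realized + 1e-12) {
          best <<- list(counts = counts, realized = realized,
                        profit = profit, idx = idx)
        }
        # lexicographic tie-break: enumeration order is lexicographic, so
        # the first candidate at a given objective value wins
      }
      return(invisible())
    }
    for (i in start:n) {
      idx[pos] <<- i
      rec(pos + 1L, i)
    }
  }
  rec(1L, 1L)
  if (is.null(best)) return(no_solution(expectation))
  make_solution(best$counts, obj, best$realized, best$profit, expectation,
                TRUE)
}

#' Pareto frontier of landscape solutions across profit expectations
#'
#' Runs the genetic algorithm once per profit expectation (each with its
#' own seed substream) and post-hoc repairs monotonicity: because feasible
#' sets are nested, a better solution found at a higher expectation is also
#' feasible, and therefore substituted, at any lower expectation.
#'
#' @inheritParams run_ga
#' @param expectations Ascending minimum-profit levels; default
#'   `c(0, 200, 400, 600, 800, 1000)`.
#' @return An object of class `pareto_set`: list of `landscape_solution`s
#'   (named by expectation) plus a `frontier` data frame.
#' @export
pareto_frontier <- function(spec, expectations = seq(0, 1000, by = 200),
                            dataset, profits, config = ga_config(),
                            L = NULL) {
  stopifnot(!is.unsorted(expectations))
  sols <- lapply(expectations, function(e) {
    cfg <- config
    cfg$seed <- stream_seed(config$seed, paste0("ga:", e))
    run_ga(spec, e, dataset, profits, cfg, L = L)
  })
  names(sols) <- as.character(expectations)
  # monotonicity repair, high to low expectation
  for (i in rev(seq_along(sols))[-length(sols)]) {
    hi <- sols[[i]]
    lo <- sols[[i - 1]]
    if (hi$status == "ok" &&
        (lo$status != "ok" || hi$realized > lo$realized)) {
      hi$expectation <- lo$expectation
      sols[[i - 1]] <- hi
    }
  }
  frontier <- data.frame(
    expectation = expectations,
    realized = vapply(sols, function(s) s$realized, numeric(1)),
    mean_profit = vapply(sols, function(s) s$mean_profit, numeric(1)),
    feasible = vapply(sols, function(s) s$feasible, logical(1))
  )
  structure(list(solutions = sols, frontier = frontier,
                 spec = spec, config = config),
            class = "pareto_set")
}

#' @export
print.pareto_set <- function(x, ...) {
  cat("Pareto frontier (", x$spec$kind,
      if (!is.null(x$spec$target)) paste0(": ", x$spec$target), ")\n",
      sep = "")
  print(x$frontier, row.names = FALSE)
  invisible(x)
}

#' Land-use composition shares of a landscape solution
#'
#' @param solution A `landscape_solution`.
#' @return Named numeric vector of per-land-use slot shares (sums to 1).
#' @export
composition_shares <- function(solution) {
  stopifnot(inherits(solution, "landscape_solution"))
  if (solution$status != "ok") {
    stop("domain error: no composition for a no-solution result",
         call. = FALSE)
  }
  solution$shares
}
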