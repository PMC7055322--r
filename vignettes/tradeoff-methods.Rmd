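---
title: "Methods: profit estimation, SIMEX smoothing, threshold indices and landscape optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profit estimation, SIMEX smoothing, threshold indices and landscape optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ecoprofit` implements a plot-based analysis of economic–ecological
trade-offs in mosaic agricultural landscapes. The pipeline links four
stages: (1) estimating plot-level profits, with their uncertainty, from a
household yield–profit survey; (2) regressing biodiversity and
ecosystem-function responses on those estimated profits with penalized
splines, corrected for the profits' measurement error by
simulation–extrapolation (SIMEX); (3) condensing many taxa and function
indicators into threshold-based multidiversity and multifunctionality
indices; and (4) searching for landscape compositions that maximize an
ecological objective under a minimum-profit constraint with a binary
genetic algorithm. A seeded synthetic-data generator emulating the
underlying study design makes every stage testable without field data.

This vignette explains the models, their assumptions, the tunable
parameters, and the numerical and design choices that were genuinely open.

## The emulated study design

The generator reproduces the statistical structure of a 32-plot design:
two landscape blocks, four land-use systems — primary degraded lowland
rainforest (F), jungle rubber agroforestry (J), rubber monoculture (R) and
oil palm monoculture (O) — and four replicate 50 m × 50 m plots per system
and block. Per plot it simulates:

* **Yields** (kg ha⁻¹ yr⁻¹) per cropped system, normal with configured
  mean and spread, truncated at zero (truncation rather than resampling
  keeps the draws reproducible under a single stream); forest yields are
  exactly 0. Defaults: J 550 ± 140 and R 900 ± 220 (dry rubber), O
  18 000 ± 3 000 (fresh fruit bunches) — magnitudes typical of smallholder
  rubber and oil palm.
* **Species incidence** for 14 taxonomic groups. Each group has a species
  pool split into a forest pool and a non-forest pool; forest plots draw
  only from the forest pool, converted plots draw a configurable fraction
  (`forest_overlap`) of their expected richness from the forest pool and
  the remainder from the non-forest pool. Species enter plots as
  independent Bernoulli draws, so expected plot richness equals the
  configured land-use mean; the distributional family (Poisson–binomial
  richness) is a modelling choice of this package, not a claim about any
  field system. Richness defaults decline from forest/agroforestry to the
  monocultures for most groups, with soil prokaryotes flat-to-increasing —
  the pattern of partial species turnover with habitat generalists
  replacing forest species. Four groups emulate incomplete sampling
  (two groups on 30 plots, two on 31) via `NA` rows.
* **36 function indicators in 10 ecosystem functions** (carbon stocks,
  NPP, decomposition, soil respiration, soil fertility, greenhouse-gas and
  nutrient-leaching fluxes, transpiration, microclimate), each a land-use
  mean plus Gaussian noise, with a `higher_better`/`lower_better`
  direction flag. Undesirable fluxes increase toward the monocultures;
  fertility improves toward the fertilized oil palm; transpiration is
  U-shaped.
* **A 701-household survey** with per-crop linear yield–profit relations
  `profit = a + b·yield + e` and residual spread growing proportionally
  with yield, `sd(e) = γ·yield`.

All randomness flows from one root seed through named substreams
(`stream_seed()`), so adding or reordering generators never perturbs the
draws of the others.

What the generator deliberately does *not* emulate: spatial structure and
plot adjacency, temporal dynamics, abundance (incidence only), and any
correlation between a plot's richness and its yield beyond what both
inherit from land use. Passing tests therefore demonstrate that the
*methods* behave correctly under the assumed structure, not that the
defaults reproduce any particular field system's numbers.

## Profit estimation with heteroscedastic measurement error

Plot profits are not observed; they are predicted from plot yields via
per-crop ordinary least squares on the household survey. The residual
spread around those lines grows with yield, and the prediction transfers
that uncertainty to the plots: each plot gets a profit mean
`μ = a + b·yield` and a measurement-error variance `σ²ₑ = v(yield)`.
Forest plots are assigned profit 0 with zero error variance.

The variance function is parameterized as `sd(e) = g·yield`. The form is
a deliberate choice: it is the simplest specification that is zero at zero
yield (so the forest reference carries no error), non-negative everywhere,
and monotone in yield. `g` is estimated by regressing absolute residuals
through the origin on yield and rescaling by √(π/2), the Gaussian
correction for `E|e| = sd·√(2/π)`; the absolute-residual estimator is less
sensitive to heavy-tailed residuals than regressing squared residuals at
a few hundred households per crop.

## Penalized-spline smooths and SIMEX correction

Responses are regressed on estimated profit with penalized splines: a
cubic B-spline basis with five interior knots at profit quantiles and a
second-order difference penalty on the coefficients. Species richness uses
a negative-binomial family (log link) to accommodate overdispersed counts;
indicators use a Gaussian family. The smoothing weight is selected by
generalized cross-validation on the naive fit; the negative-binomial
dispersion θ is estimated by maximum likelihood on the naive fit. Both are
then **held fixed** across all SIMEX replicates: letting the smoothing
level or dispersion re-adapt to each noisier replicate would confound the
bias–versus–error-variance relationship that the extrapolation models.

Because the predictor is estimated, naive smooths are biased (attenuation:
added predictor noise flattens slopes). SIMEX exploits this directly. For
each inflation factor λ on a grid of 10 equidistant values from 0.1 to 3,
extra noise `N(0, λ·σ²ₑᵢ)` is added to the profits and the smoother refit;
averaging B = 200 replicates estimates `G(λ)`, the expected curve under
error variance `(1 + λ)σ²ₑ`. A quadratic in λ is then fitted pointwise by
least squares to `{(0, naive)} ∪ {(λⱼ, G(λⱼ))}` and evaluated at λ = −1 —
the zero-measurement-error limit, which is the corrected curve.

Numerical and design choices:

* **What is extrapolated.** Fitted values on a fixed evaluation grid, not
  spline coefficients: coefficient-space extrapolation is basis-dependent,
  and the fitted curves are what the analysis reports. The knot span is
  widened by three standard deviations of the largest added noise so
  replicate predictors stay inside the basis support (values beyond it are
  clamped to the boundary).
* **Confidence band.** The extrapolated value at each grid point is a
  fixed linear combination `w·G` of the per-λ means, so its Monte-Carlo
  variance is `Σ wⱼ² Var(Ḡⱼ)`; the reported 95% band adds this to the
  naive fit's smoothing variance (delta-method construction). The band is
  an implementation choice of this package.
* **Trend summaries.** `simex_slope()` summarizes a curve's average trend
  by OLS of the curve on the grid, by default over the central 80% of the
  observed predictor: penalized smooths are shrunk toward flatness where
  data run out, and the untrimmed summary understates both the naive and
  the corrected slope. On the linear-Gaussian benchmark (slope 1,
  predictor variance 1, error variance 0.5) the trimmed naive slope
  matches the analytic attenuation factor 1/(1 + 0.5) ≈ 0.667 and the
  corrected slope approaches the analytic quadratic-extrapolant limit
  0.87 — SIMEX with a finite λ grid and polynomial extrapolant removes
  most, not all, of the attenuation bias.
* **Degenerate inputs.** Zero error variances reproduce the naive curve
  exactly; ties in profits are permitted (no jittering); constant
  predictors are rejected as a degenerate design.

## Multidiversity and multifunctionality

Each group's (or direction-corrected indicator's) 100% reference is the
mean of its five highest plot values — averaging the top five damps single
outliers. A plot's **multidiversity** at threshold *t* is the proportion
of groups measured on the plot whose richness reaches `t × reference`
(groups not sampled on a plot are excluded from numerator and
denominator). **Multifunctionality** weights each indicator by the inverse
of its function's indicator count (an 8-indicator function weights each at
12.5%), so every function contributes equally, and divides by the number
of functions; the pass rule is `≥`, so exact attainment counts.

Two scale choices matter:

* *Direction correction* uses range reflection `x' = max + min − x` rather
  than a reciprocal: fluxes can be zero (where a reciprocal is undefined),
  and the construction only needs order reversal before thresholding.
  Reflection is an involution and preserves the range.
* *Negative scales.* A proportional threshold ("reaches t% of the
  reference") presumes a ratio scale. Direction-corrected indicators whose
  values reach below zero (e.g. net CH₄ flux) are shifted to a zero
  minimum before levels are computed; without the shift the index is not
  monotone in the threshold.

Indices are computed across the full threshold range, by default 99 steps
of one percentage point from 1% to 99% (the step is configurable). Each
index–profit relation is then summarized per threshold by simple linear
regression of the index on the *raw* predicted profits, reported per
100 USD ha⁻¹ yr⁻¹ with a 95% confidence interval.

## Landscape optimization

A conceptual landscape is a multiset: L slots (default 32, reduced to the
available-plot count for incompletely sampled groups) filled **with
replacement** from the study plots. The search space for 32 slots over 32
plots is `C(63, 32) = 916 312 070 471 295 267 ≈ 9.16 × 10¹⁷` compositions
— computed in exact big-integer arithmetic, since the count exceeds what
doubles represent exactly. Objectives, all scaled to [0, 1]:

* `group_richness` — union richness over the *distinct* included plots
  divided by the group's species total (duplicates add no species; 1 means
  every sampled species of the group is present);
* `function_level` — the mean over slots (with multiplicity) of the
  plot's min–max-standardized, direction-corrected indicator mean for one
  function;
* `multidiversity` / `multifunctionality` — the multiplicity-weighted
  mean of the plot-level index at a configurable threshold (default 50%).
  The landscape-level form of these indices is not uniquely determined by
  the plot-level definition; the plot-mean is the implemented default.

A candidate is feasible when its multiplicity-weighted mean plot profit
reaches the profit expectation (0–1000 USD ha⁻¹ yr⁻¹ grid, step 200).

The optimizer is a binary genetic algorithm with the replication encoding:
each plot's inclusion gene is replicated L times, giving an `n²`-gene
chromosome (1024 for 32 plots), gene *g* mapping to plot `g mod n`.
Choices the encoding leaves open were fixed as follows: chromosomes are
*repaired* to exactly L set genes by seeded random flips before evaluation
(keeping the whole population valid in encoding space, rather than
penalizing counts in the fitness); infeasible-profit solutions receive a
negative fitness that shrinks with the shortfall — constraint dominance
that discards them relative to any feasible solution while still guiding
the population toward feasibility. Selection is rank-proportional with 20%
elitism, crossover single-point, mutation bit-flip at rate
`1/(chromosome length + 1)`; population 500, 100 generations. All runs are
deterministic given their seed.

Two safeguards back the heuristic. `brute_force_optimize()` enumerates
every multiset exactly for small instances (budget-limited, ties broken
toward the lexicographically smallest multiset) and serves as the oracle
in tests: on 6-plot/4-slot instances (126 candidates) the GA attains the
enumerated optimum in 20 of 20 seeded runs. And `pareto_frontier()`
repairs monotonicity post hoc: feasible sets are nested in the
expectation, so a better solution found at a higher expectation replaces a
worse one at a lower expectation. If no plot can meet an expectation, the
run reports an explicit no-solution status rather than a silently
infeasible answer.

## Problem sizes used in the test suite

The packaged tests exercise the study-scale configuration directly: the
32-plot design with all 14 groups and 36 indicators, SIMEX at B = 200
with the 10-value λ grid, and the GA at population 500 × 100 generations
for the six-expectation frontier. Monte-Carlo properties use 100 seeded
replicates for the attenuation-recovery and sign-structure checks, 20 for
GA–oracle equivalence; the acceptance script reports the same quantities
at 30 replicates. These sizes were chosen so the full suite completes in
a few minutes on one CPU while keeping Monte-Carlo standard errors well
below the margins being asserted.

## Known limitations

* The variance law `sd(e) = g·yield` is linear by construction; if real
  residual spread grows non-linearly, plot error variances are mildly
  mis-stated (the SIMEX machinery itself accepts any non-negative
  per-plot variance).
* SIMEX with a quadratic extrapolant is approximately, not exactly,
  unbiased; the linear benchmark shows ~60% bias removal under strong
  error (error variance half the signal variance).
* The GA provides no optimality certificate at full scale; equivalence is
  verified only where enumeration is feasible.
* Landscape objectives are compositional: no spatial arrangement,
  adjacency or spillover effects.
* Indices depend on the observed maxima through the top-five reference;
  adding plots can change all index values retrospectively.
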