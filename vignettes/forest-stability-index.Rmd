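---
title: "Relative tree density, the stability index, and its estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative tree density, the stability index, and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic generator does and does not emulate,
numerical choices, and known limitations. It states no empirical result that
the test suite does not itself compute.

## Why relative density

Absolute live-tree density falls as stands age even when nothing is wrong:
growing trees demand more space, and density-dependent mortality
(self-thinning) removes stems along a power-law boundary. Any index of
population change built on absolute density therefore confounds stand
development with genuine decline. The stability index used here works in
relative density — observed density as a fraction of the maximum a stand of
that tree-size structure could support — so a stand moving along the
self-thinning boundary scores exactly zero change (`fsi()` of the points on
`simulate_self_thinning_track()` is identically 0; the suite asserts this).

## The maximum size-density frontier

`fit_frontier()` models the boundary as `N_max(S̄) = a_i·S̄^{r_i}` per
forest community type *i*, fitted in log–log space as the conditional 99th
percentile of stems/ha given mean tree basal area (m²). Choices that
matter:

* **Quantile machinery.** Bayesian quantile regression through the
  asymmetric-Laplace working likelihood at τ = 0.99, sampled via its
  exponential scale-mixture representation in JAGS. τ is a parameter; 0.99
  is the default because the boundary is an attainability frontier that a
  small fraction (~1%) of stands legitimately exceeds.
* **Priors.** Population intercept `log a ~ normal(7, 1)` and slope
  `r ~ normal(−0.8025, 0.1)`. The slope prior center is the Reineke-type
  exponent translated to a mean-basal-area size index (TPH ∝ QMD^−1.605
  implies exponent −0.8025 on mean basal area); its sign is negative by the
  frontier's definition. These are informative on purpose: an extreme
  conditional quantile is weakly identified in any single dataset, and
  decades of size-density research pin the plausible range tightly.
* **Hierarchy.** Per-type intercepts and slopes are drawn around the
  population values with half-normal hyperpriors on the deviation scales —
  scale 1 for intercepts, 0.1 for slopes. The slope scale is deliberately
  the same magnitude as the slope prior sd: across forest community types
  the self-thinning exponent varies by hundredths, not units, and a loose
  scale lets a type with few near-boundary stands drift along the
  intercept–slope ridge instead of borrowing strength.
* **Sampler parameterization.** The model is sampled against the centered
  covariate `log S̄ − mean(log S̄)` with hierarchically centered random
  effects, and the intercept is transformed back to S̄ = 1 for reporting.
  The uncentered intercept sits far outside the data (mean log S̄ ≈ −3.5),
  so sampling it directly creates a posterior ridge that stalls single-site
  updates; centering removes it. Split R-hat is computed on the per-type
  curves and the AL scale — the quantities `predict()` uses; the population
  means and deviation scales mix slowly whenever few types are observed,
  which does not affect the reported curves, but all R-hats are kept in
  `$diagnostics`.
* **Defaults.** 4 chains × (1000 adapt + 1500 warmup + 1250 draws) keeps
  5000 retained draws, the draw count the downstream attribution stage also
  uses. Point predictions use posterior medians (robust under the skewed AL
  posterior); the full draws are kept on the object.

Training stands must be credible observations of the *undisturbed* boundary:
`filter_frontier_training()` keeps the most recent census of each plot only
if no disturbance or silvicultural treatment is in evidence during the
remeasurement interval or the preceding five years and the diameter
distribution is approximately normal — moment-coefficient skewness (g1 with
n-denominators, unweighted DBH list) inside the closed interval [−1, 1].
Binary FIA-style disturbance flags carry no event year, so any disturbance
flagged at the *previous* census also excludes the plot: a conservative
reading of the five-year look-back. Stands with fewer than three measured
stems cannot be screened for normality and are excluded from training
(they remain in change analysis, where no normality assumption is needed).

## The stability index

`relative_density()` sums tree-level relative densities
`Σ_h N_h / N_max(S_h)`: each tree's represented stems/ha divided by the
maximum density of a stand whose *average* tree size equals that tree's own
size. Two consequences, both asserted exactly by the suite:

* additivity — the ten size-class partitions of a species' RD sum to the
  whole-species RD to floating-point accuracy, so size-class change
  decomposes the species change exactly;
* aggregation-bias direction — the aggregate index `TPH/N_max(S̄)` is ≥ the
  tree-level sum whenever |r| < 1, with equality only for equal-sized trees
  (Jensen's inequality applied to the concave map `S ↦ S^{−r}`), so the
  tree-level definition never inherits the aggregate index's overestimate
  in irregularly structured stands.

RD is not capped at 1: the frontier is a 99th percentile and ~1% of stands
genuinely sit above it; capping would bias change estimates downward.

`fsi()` is `(RD_t2 − RD_t1)/Δt` (per year; positive = expansion, and range
expansion from absence enters as positive change from RD = 0).
`percent_fsi()` divides the *population mean* FSI by the *population mean*
baseline RD — a ratio of means, never a mean of plot-level ratios, because
plot-level baselines of zero occur by design. Total study-period change is
the linear product `%FSI × years` (so −5.56 %/yr over 18 years is complete
loss); the package never compounds.

Size classes are deciles of the observed initial-census diameter
distribution of each species within each of seven site productivity
classes, raw-sample quantiles (type 7), unweighted — the screen and the
classes describe the measured sample, and no expansion weighting is stated
for either. Classes are half-open `[q_{k−1}, q_k)` with the top class
closed above; a species × productivity stratum absent from the table falls
back to species-level deciles, flagged.

## Population estimation

Plot-level FSI records are combined with the standard post-stratified
estimators (`mean = Σ W_s ȳ_s`, `var = Σ W_s² s_s²/n_s`), stratum weights
renormalized over sampled strata, single-plot strata collapsed into the
largest-weight sampled stratum (variance needs n ≥ 2). Annual remeasurement
panels (8 panels, 2011–2018 in the emulated design) are combined with equal
weight: mean of panel means, variance `Σ var_p / P²`. Classification uses
the normal-theory 95% interval: declining if entirely below zero, expanding
if above, stable otherwise — an exhaustive, exclusive trichotomy. A species'
range is the set of ecoregion subsections with at least one detection at
either census; range-average estimates draw on every eligible plot in those
subsections, with zeros where the species is absent. The %FSI standard
error uses a first-order delta method for the ratio of two correlated means
with the plot-level covariance carried through both the post-stratified and
panel-combination stages; the paper-style ± values this mirrors are treated
as standard errors.

## Disturbance attribution

Severity: per-species normal regression of plot-level FSI on the three
binary disturbance indicators (additive; simultaneous disturbances
allowed), flat normal(0, 10²) priors, uniform(1e-6, 10) on the residual SD
(the floor keeps the posterior proper for degenerate zero-variance inputs —
the exact-zero-change synthetic landscape is a legitimate test input).
Probability: the binary interval flag is modeled as
`binomial(round(Δt), ψ)` with a beta(1, 1) prior; rounding Δt to integer
trials loses nothing material at ~10-year intervals. The two posteriors are
fitted independently and multiplied draw by draw — a two-stage product, not
a joint model — then standardized by the species' mean baseline RD.

The binomial-flag formulation censors multi-event intervals to one event,
so ψ is biased downward when events are common — at ψ = 0.03 and Δt = 10
the flag rate implies ≈ 0.0263 rather than 0.03. The model is implemented
as stated and the recovery tests record the shortfall rather than correct
it. Species are fitted jointly with species-indexed parameters, which is
identical to independent per-species fits since nothing pools across
species.

## The synthetic landscape

`generate_landscape()` emulates the features the estimators rely on: paired
censuses (mean interval 9.78 years, second census in 2011–2018 within a
2001–2018 window), forest-type-specific power-law frontiers, binary
fire/insect/disease interval flags arising from annual Bernoulli events,
treatment flags, stratum labels with known area weights, and nested
division/subsection labels with optional per-species range restriction.
Stand stocking (total RD at first census) is a Beta(3, 2) rescaled so its
upper 1% tail crosses the frontier exactly — undisturbed even-aged stands
accumulate near the self-thinning boundary, which is both the regime the
method presumes and what makes a 99th-percentile frontier estimable at
realistic sample sizes. Tree lists are drawn from a lognormal diameter
family (sdlog 0.12 in "normal" mode, 0.8 in "skewed" mode) rescaled so the
realized mean tree basal area matches the stand's size index exactly;
rescaling preserves skewness, so the modes control the screen's pass rate.

The second census applies, per species, `Δt · (drift + Σ β_l x_l + ε)`,
`ε ~ N(0, ς²)` with ς = 0.005/yr by default, truncated so RD never goes
negative, and rescales the species' expansion factors accordingly. Two
deliberate simplifications: tree *sizes* do not change between censuses
(the index depends only on relative-density change; growth realism adds
nothing the estimators can detect), and plot-level disturbance is drawn at
the rates of the forest type's dominant species (a plot has one disturbance
history). Consequently passing tests demonstrate correct estimation of the
generating process, not robustness to measurement error, spatial
autocorrelation, partial-plot conditions, or growth–mortality micro-
dynamics, none of which the generator emulates. `expected_baseline_rd()`
gives the closed-form species-level mean baseline RD, which is how the
recovery suite constructs drifts targeting a known %FSI.

All randomness flows through per-plot substreams keyed on the seed and plot
index, so identical configs are byte-identical and subsetting plots does
not reshuffle the remainder.

## Problem sizes and numerical choices

The validation suite runs at deliberate desk scale: 2000 plots for frontier
recovery and exceedance calibration, 800 for end-to-end classification
recovery, hundreds of replicates for the exact partition properties and CI
coverage, 5000 MCMC draws per fit. Exact identities are asserted to 1e-12
relative tolerance; Monte-Carlo comparisons use 3 effective-sample-size
standard errors. Degenerate inputs are defined, not special-cased away:
empty tree lists give RD 0, empty stands give undefined (`NA`) mean size
and skewness, a zero baseline makes %FSI an explicit error, and ties in
size-class boundaries assign downward (half-open intervals).

## Limitations

The frontier is a single power law per forest type — no segmented or
climate-modulated frontiers. Estimation implements the textbook
post-stratified and equal-weight panel estimators, not a full inventory
system's temporally weighted variants or finite-population corrections.
Attribution is associational: severity is a conditional mean difference
over ~decadal intervals (immediate impact plus several years of response),
not a causal effect, and no spatial random effects or disturbance
interactions are modeled. The disturbance-probability model inherits the
binary-flag censoring bias described above.
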