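# fsindex

Quantifying change in tree populations from remeasured forest-inventory
plots.

Tree demographic rates (mortality, growth, recruitment) are confounded by
stand development: live-tree density falls as trees grow even in perfectly
healthy stands, following allometric self-thinning laws. `fsindex`
implements a demographic index that removes this confounding by working in
*relative* density — the ratio of observed tree density to the maximum
theoretical density a stand could support given its tree sizes — and
measures population change as the annual change in relative density between
successive plot censuses. It is aimed at analysts of national
forest-inventory data (FIA-style remeasured plot networks) and at simulation
studies of such analyses.

## The model

**Maximum size-density frontier.** For forest community type *i*, the
maximum live-tree density attainable at mean tree basal area S̄ is the power
law

    N_max(S̄) = a_i · S̄^{r_i},   r_i < 0,

fitted as the 99th percentile of TPH conditional on S̄ in log–log space: a
Bayesian quantile regression (asymmetric-Laplace working likelihood,
τ = 0.99) with intercept and slope varying by forest type, and informative
normal priors on the intercept (μ = 7, σ = 1) and slope (μ = −0.8025,
σ = 0.1) reflecting Reineke-type scaling. Training stands are undisturbed,
untreated, and have approximately normal diameter distributions (moment
skewness in [−1, 1]).

**Relative density and the stability index.** The relative density of a
population *j* (a species, optionally within a diameter size class) in a
stand is summed tree by tree,

    RD_j = Σ_h N_h / N_max(S_h),

each tree's represented density divided by the maximum density of a stand
whose average tree size equals that tree's own size. This partition makes RD
exactly additive over size classes and avoids the aggregation bias of
`TPH / N_max(mean S)` in unevenly sized stands. Change between censuses is

    FSI = (RD_t2 − RD_t1) / Δt,     %FSI = 100 · FSI / RD_t1,

with %FSI computed at the population level as a ratio of means. Population
status follows the 95% confidence interval of the range-averaged FSI
(post-stratified estimators combined over annual remeasurement panels with
equal weight): declining below zero, expanding above, stable otherwise.

**Disturbance attribution.** Plot-level FSI of species *j* responds to
binary fire/insect/disease interval flags,

    y_jk ~ normal(α_j + Σ_l β_jl · x_lk, ς_j²),
    x_lk ~ binomial(Δt_k, ψ_jl),

so β (severity) is the mean FSI difference between disturbed and undisturbed
plots and ψ the annual disturbance probability. The population-level effect
is the draw-wise product β·ψ, standardized by the species' mean baseline
relative density (% per year); significance is a 95% credible interval
excluding zero. MCMC throughout is JAGS (5000 retained draws by default).

A seeded synthetic-landscape generator (`generate_landscape()`) produces
FIA-like paired censuses with known frontier, drift, severity and
probability parameters so every stage can be validated by parameter
recovery.

## Worked example

A 400-plot synthetic landscape with two species; fire occurs on species
101's sites at annual probability 0.04 and removes 0.02 relative density
per year, species 202 is untouched:

```r
library(fsindex)
cfg <- landscape_config(
  n_plots = 400, seed = 42, species = c(101L, 202L),
  species_weights = matrix(0.5, 3, 2),
  psi  = matrix(c(0.04, 0.01, 0, 0, 0, 0), 2, 3),
  beta = matrix(c(-0.02, 0,    0, 0, 0, 0), 2, 3))
land <- generate_landscape(cfg)

frontier <- fit_frontier(filter_frontier_training(land$inventory)$kept,
                         seed = 1)
frontier
#> Maximum size-density frontier (tau = 0.99, 5000 draws, 263 stands)
#>   forest_type log_a      a       r
#> 1        FT01 7.259 1420.3 -0.7532
#> 2        FT02 7.050 1152.8 -0.8018
#> 3        FT03 6.847  940.8 -0.8618
#> max split R-hat: 1.047 (converged)

records <- population_change(land$inventory, frontier)
pairs   <- filter_change_analysis(land$inventory)$kept
scheme  <- stratification_scheme(land$scheme$stratum_id, land$scheme$W)
grouped_estimates(records, pairs, scheme)
#>   species_code  mean_fsi percent_fsi percent_fsi_se classification n_plots
#> 1          101 -0.005803      -1.973         0.1843      declining     400
#> 2          202  0.000538       0.185         0.0849      expanding     400
```

The generating conditions imply roughly −2 %/yr for species 101
(fire flagged on ≈ 1 − 0.96^10 ≈ a third of intervals, each stripping
0.02/0.32 ≈ 6% of baseline relative density per year): the estimate
−1.97 ± 0.18 recovers it. Species 202 is truly stable; its weak
"expanding" call is a borderline two-standard-error call, the kind the
classification rule will make about 5% of the time.

```r
obs  <- disturbance_observations(records)
sev  <- fit_severity(obs, seed = 2)
prob <- fit_probability(obs, seed = 3)
standardized_effect(sev, prob, tapply(obs$rd_t1, obs$species_code, mean))
#>   species_code disturbance     effect standardized    lo95    hi95 significant
#> 1          101        fire -6.008e-04      -0.2019 -0.2398 -0.1694        TRUE
#> 2          101      insect -7.629e-07      -0.0003 -2.6402  2.5732       FALSE
#> ...
```

Fire on species 101 is the only significant driver: −0.20 %/yr of relative
density attributable to fire, matching the generating product
β·ψ / RD ≈ (−0.02 · 0.04 / 0.32) · 100 ≈ −0.25 with the binary-flag
censoring of multi-event intervals accounting for the small shortfall.

An end-to-end YAML-driven run (synthesis → filters → frontier → records →
estimates → attribution, with a JSON manifest) is available as
`run_pipeline()` or the thin CLI `inst/cli/fsi.R`.

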