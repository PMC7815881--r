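# Builders for small hand-made inventories and independent oracles used
# across the test files.

plot_row <- function(id, prev = NA_character_, year, ft = "FT01", sc = 3L,
                     div = "DIV1", sub = "SUBA", stratum = "S1",
                     fire = 0L, insect = 0L, disease = 0L, other = 0L,
                     treated = 0L, trt_yr = NA_real_) {
  data.frame(plot_id = id, prev_plot_id = prev, census_year = year,
             forest_type = ft, site_class = sc, ecoregion_division = div,
             ecoregion_subsection = sub, stratum_id = stratum,
             fire = fire, insect = insect, disease = disease,
             other_disturbance = other, treated = treated,
             treatment_year = trt_yr, stringsAsFactors = FALSE)
}

tree_rows <- function(plot_id, dbh, density_factor, species = 101L,
                      status = "live") {
  n <- length(dbh)
  data.frame(plot_id = plot_id,
             tree_id = paste0(plot_id, "_T", seq_len(n)),
             species_code = rep_len(species, n), dbh = dbh,
             status = rep_len(status, n),
             density_factor = rep_len(density_factor, n),
             basal_area = basal_area(dbh), stringsAsFactors = FALSE)
}

new_inventory <- function(plots, trees) {
  plots$paired <- !is.na(plots$prev_plot_id) &
    plots$prev_plot_id %in% plots$plot_id
  idx <- match(plots$prev_plot_id, plots$plot_id)
  plots$prev_year <- ifelse(plots$paired, plots$census_year[idx], NA_real_)
  plots$delta_t <- plots$census_year - plots$prev_year
  structure(list(plots = plots, trees = trees), class = "fsi_inventory")
}

# independent check-loss quantile regression (Koenker loss via Nelder-Mead),
# used as the frequentist oracle for the Bayesian frontier fit
oracle_qr <- function(y, x, tau = 0.99, start = c(7, -0.8)) {
  rho <- function(u) u * (tau - (u < 0))
  f <- function(p) sum(rho(y - p[1] - p[2] * x))
  stats::optim(start, f, method = "Nelder-Mead",
               control = list(maxit = 10000, reltol = 1e-12))$par
}

# effective-sample-size-based Monte Carlo standard error of a draw vector
mc_se <- function(draws) {
  ess <- tryCatch(coda::effectiveSize(coda::as.mcmc(draws)),
                  error = function(e) length(draws))
  stats::sd(draws) / sqrt(max(1, ess))
}

# random stand tree list for property tests
random_stand <- function(n = NULL, rng_n = 3:25) {
  n <- if (is.null(n)) sample(rng_n, 1) else n
  tree_rows("X", dbh = stats::runif(n, 3, 90),
            density_factor = stats::runif(n, 1, 120))
}
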