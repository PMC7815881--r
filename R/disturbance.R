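#' Observations for disturbance attribution
#'
#' Assembles the plot x species table the disturbance models consume: the
#' FSI of species j on plot k, the interval's binary fire/insect/disease
#' flags, and the remeasurement interval length.
#'
#' @param records output of [population_change()] (whole-species records,
#'   not size-class partitions).
#' @return data frame with `species_code`, `plot_id`, `y` (FSI, per year),
#'   `fire`, `insect`, `disease`, `delta_t`, `rd_t1`.
#' @export
disturbance_observations <- function(records) {
  stopifnot(all(c("species_code", "fsi", "fire", "insect", "disease",
                  "delta_t") %in% names(records)))
  data.frame(species_code = records$species_code,
             plot_id = records$plot_id, y = records$fsi,
             fire = records$fire, insect = records$insect,
             disease = records$disease, delta_t = records$delta_t,
             rd_t1 = records$rd_t1, stringsAsFactors = FALSE)
}

DISTURBANCE_TYPES <- c("fire", "insect", "disease")

#' Fit the disturbance-severity model
#'
#' Per-species normal linear model of the plot-level FSI on the three binary
#' disturbance indicators,
#' `y_jk ~ normal(alpha_j + sum_l beta_jl * x_lk, sigma_j^2)`: `beta_jl` is
#' the disturbance severity — the mean difference in FSI between disturbed
#' and undisturbed plots of species j. Priors are uninformative:
#' normal(0, 10^2) on intercepts and coefficients, uniform(0, 10) on the
#' residual SD. Species are fit jointly with species-indexed parameters (no
#' pooling across species). A (species, disturbance) cell with no disturbed
#' plots is prior-dominated and flagged `unidentified`. The uniform scale
#' prior is floored at 1e-6 so degenerate (zero-variance) inputs keep a
#' proper posterior.
#'
#' @param obs a [disturbance_observations()] data frame.
#' @param n_chains,n_adapt,n_warmup,n_iter MCMC settings (default 4 chains x
#'   1250 retained draws = 5000).
#' @param seed integer seed.
#' @return object of class `"fsi_severity"`: draw matrices `alpha`
#'   (draws x species), `beta` (draws x species x 3), `sigma`, a summary
#'   table, `unidentified` flags and R-hat diagnostics.
#' @export
fit_severity <- function(obs, n_chains = 4, n_adapt = 500, n_warmup = 1000,
                         n_iter = 1250, seed = 1) {
  species <- sort(unique(obs$species_code))
  J <- length(species)
  sp_i <- match(obs$species_code, species)
  if (any(table(factor(sp_i, levels = seq_len(J))) < 2))
    stop("each species needs at least 2 plots", call. = FALSE)
  X <- as.matrix(obs[, DISTURBANCE_TYPES])
  model <- "
model {
  for (k in 1:n) {
    y[k] ~ dnorm(alpha[sp[k]] + inprod(beta[sp[k], ], x[k, ]),
                 prec[sp[k]])
  }
  for (j in 1:J) {
    alpha[j] ~ dnorm(0, 0.01)
    for (l in 1:3) { beta[j, l] ~ dnorm(0, 0.01) }
    sigma[j] ~ dunif(1.0E-6, 10)
    prec[j] <- pow(sigma[j], -2)
  }
}"
  inits <- lapply(seq_len(n_chains), function(ch)
    list(alpha = rep(0, J), beta = matrix(0, J, 3), sigma = rep(0.01, J),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 211 + ch) %% 2147483647))
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = obs$y, x = X, sp = sp_i,
                                      n = nrow(obs), J = J),
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  stats::update(jm, n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("alpha", "beta", "sigma"),
                              n.iter = n_iter, progress.bar = "none")
  rhat <- tryCatch(
    coda::gelman.diag(samp, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) NA_real_)
  draws <- as.matrix(samp)
  nd <- nrow(draws)
  # JAGS drops the index from length-one vector nodes
  pick <- function(nm, alt) if (nm %in% colnames(draws)) draws[, nm] else
    draws[, alt]
  alpha <- sapply(seq_len(J), function(j)
    pick(sprintf("alpha[%d]", j), "alpha"))
  alpha <- matrix(alpha, nd, J, dimnames = list(NULL, species))
  beta <- array(NA_real_, c(nd, J, 3),
                dimnames = list(NULL, species, DISTURBANCE_TYPES))
  for (j in seq_len(J)) for (l in 1:3)
    beta[, j, l] <- pick(sprintf("beta[%d,%d]", j, l),
                         sprintf("beta[%d]", l))
  sigma <- sapply(seq_len(J), function(j)
    pick(sprintf("sigma[%d]", j), "sigma"))
  sigma <- matrix(sigma, nd, J, dimnames = list(NULL, species))
  unid <- matrix(FALSE, J, 3, dimnames = list(species, DISTURBANCE_TYPES))
  for (j in seq_len(J)) for (l in 1:3)
    unid[j, l] <- sum(X[sp_i == j, l]) == 0
  structure(list(species = species, alpha = alpha, beta = beta,
                 sigma = sigma, unidentified = unid,
                 diagnostics = list(rhat = rhat,
                                    max_rhat = suppressWarnings(
                                      max(rhat, na.rm = TRUE))),
                 n_draws = nd, call = match.call()),
            class = "fsi_severity")
}

#' @export
coef.fsi_severity <- function(object, ...) {
  data.frame(species_code = rep(object$species, each = 3),
             disturbance = rep(DISTURBANCE_TYPES, length(object$species)),
             beta = as.vector(t(apply(object$beta, c(2, 3), stats::mean))),
             stringsAsFactors = FALSE)
}

#' @export
print.fsi_severity <- function(x, ...) {
  cat("Disturbance severity model:", length(x$species), "species,",
      x$n_draws, "draws\n")
  b <- apply(x$beta, c(2, 3), stats::median)
  print(round(b, 5))
  if (any(x$unidentified))
    cat("unidentified (no disturbed plots):",
        paste(which(x$unidentified, arr.ind = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Fit annual disturbance probabilities
#'
#' Models the binary interval flag of disturbance l on plot k as a binomial
#' count over the remeasurement interval,
#' `x_lk ~ binomial(round(delta_t_k), psi_jl)`, with a beta(1, 1) prior on
#' each species x disturbance annual probability. Note the flag censors
#' multi-event intervals to 1, which biases psi downward when events are
#' common; the model is used as stated.
#'
#' @param obs a [disturbance_observations()] data frame.
#' @param n_chains,n_adapt,n_warmup,n_iter MCMC settings (default 5000
#'   retained draws).
#' @param seed integer seed.
#' @return object of class `"fsi_probability"`: draw array `psi`
#'   (draws x species x 3) and a posterior summary table.
#' @export
fit_probability <- function(obs, n_chains = 4, n_adapt = 200,
                            n_warmup = 500, n_iter = 1250, seed = 1) {
  species <- sort(unique(obs$species_code))
  J <- length(species)
  sp_i <- match(obs$species_code, species)
  n_trials <- pmax(1L, as.integer(round(obs$delta_t)))
  X <- as.matrix(obs[, DISTURBANCE_TYPES])
  model <- "
model {
  for (k in 1:n) {
    for (l in 1:3) { x[k, l] ~ dbin(psi[sp[k], l], m[k]) }
  }
  for (j in 1:J) {
    for (l in 1:3) { psi[j, l] ~ dbeta(1, 1) }
  }
}"
  inits <- lapply(seq_len(n_chains), function(ch)
    list(psi = matrix(0.1, J, 3),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 307 + ch) %% 2147483647))
  jm <- rjags::jags.model(textConnection(model),
                          data = list(x = X, m = n_trials, sp = sp_i,
                                      n = nrow(obs), J = J),
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  stats::update(jm, n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "psi", n.iter = n_iter,
                              progress.bar = "none")
  draws <- as.matrix(samp)
  nd <- nrow(draws)
  psi <- array(NA_real_, c(nd, J, 3),
               dimnames = list(NULL, species, DISTURBANCE_TYPES))
  pick <- function(nm, alt) if (nm %in% colnames(draws)) draws[, nm] else
    draws[, alt]
  for (j in seq_len(J)) for (l in 1:3)
    psi[, j, l] <- pick(sprintf("psi[%d,%d]", j, l),
                        sprintf("psi[%d]", l))
  structure(list(species = species, psi = psi, n_draws = nd,
                 call = match.call()),
            class = "fsi_probability")
}

#' @export
print.fsi_probability <- function(x, ...) {
  cat("Annual disturbance probability model:", length(x$species),
      "species,", x$n_draws, "draws\n")
  print(round(apply(x$psi, c(2, 3), stats::median), 4))
  invisible(x)
}

#' Standardized population-level disturbance effects
#'
#' Multiplies, draw by draw, the posterior distributions of disturbance
#' severity (`beta_jl`) and annual disturbance probability (`psi_jl`) to give
#' the mean annual change in relative density attributable to each
#' disturbance type, then standardizes across species by dividing by each
#' species' average baseline relative density (x100, so the units are annual
#' percent change in relative density). An effect is significant when the
#' central 95% credible interval of the product excludes zero.
#'
#' @param severity an `"fsi_severity"` fit.
#' @param probability an `"fsi_probability"` fit (same species, same number
#'   of draws).
#' @param mean_rd_t1 named vector (by species code) of mean baseline relative
#'   density, all > 0.
#' @return object of class `"disturbance_effect"`: draw array
#'   `standardized` (draws x species x 3) and a `summary` data frame with
#'   posterior medians, 95% credible intervals and significance flags.
#' @export
standardized_effect <- function(severity, probability, mean_rd_t1) {
  stopifnot(inherits(severity, "fsi_severity"),
            inherits(probability, "fsi_probability"))
  if (!identical(severity$species, probability$species))
    stop("severity and probability fits cover different species",
         call. = FALSE)
  if (severity$n_draws != probability$n_draws)
    stop("severity and probability fits have different draw counts",
         call. = FALSE)
  species <- severity$species
  rd <- mean_rd_t1[as.character(species)]
  if (any(is.na(rd) | rd <= 0))
    stop("mean_rd_t1 must be positive for every species", call. = FALSE)
  effect <- severity$beta * probability$psi
  std <- sweep(effect, 2, rd, "/") * 100
  qs <- apply(std, c(2, 3), stats::quantile, probs = c(0.025, 0.5, 0.975))
  summ <- data.frame(
    species_code = rep(species, each = 3),
    disturbance = rep(DISTURBANCE_TYPES, length(species)),
    effect = as.vector(t(apply(effect, c(2, 3), stats::median))),
    standardized = as.vector(t(qs[2, , ])),
    lo95 = as.vector(t(qs[1, , ])),
    hi95 = as.vector(t(qs[3, , ])),
    stringsAsFactors = FALSE)
  summ$significant <- summ$lo95 > 0 | summ$hi95 < 0
  structure(list(species = species, standardized = std, effect = effect,
                 summary = summ, n_draws = severity$n_draws),
            class = "disturbance_effect")
}

#' @export
print.disturbance_effect <- function(x, ...) {
  cat("Standardized disturbance effects (% change in relative density per year)\n")
  s <- x$summary
  s$standardized <- round(s$standardized, 4)
  s$lo95 <- round(s$lo95, 4); s$hi95 <- round(s$hi95, 4)
  s$effect <- signif(s$effect, 4)
  print(s)
  invisible(x)
}
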