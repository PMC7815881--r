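make_obs <- function(n, psi = c(0.03, 0.05, 0.01), alpha = 0,
                     beta = c(-0.02, -0.01, 0.005), sigma = 0.005,
                     species = 101L, delta_t = 10L, flags = NULL) {
  if (is.null(flags))
    flags <- sapply(1:3, function(l)
      as.integer(rbinom(n, delta_t, psi[l]) > 0))
  y <- alpha + as.vector(flags %*% beta) + rnorm(n, 0, sigma)
  data.frame(species_code = species, plot_id = paste0("P", seq_len(n)),
             y = y, fire = flags[, 1], insect = flags[, 2],
             disease = flags[, 3], delta_t = delta_t,
             rd_t1 = runif(n, 0.2, 0.8), stringsAsFactors = FALSE)
}

test_that("probability posteriors match the conjugate beta closed form", {
  set.seed(101)
  for (d in 1:10) {
    n <- sample(5:25, 1)
    dts <- sample(5:14, n, replace = TRUE)
    flags <- matrix(rbinom(3 * n, 1, runif(1, 0.05, 0.6)), n, 3)
    obs <- data.frame(species_code = 7L, plot_id = paste0("P", 1:n),
                      y = 0, fire = flags[, 1], insect = flags[, 2],
                      disease = flags[, 3], delta_t = dts, rd_t1 = 0.5)
    fit <- fit_probability(obs, seed = 1000 + d)
    for (l in 1:3) {
      a <- 1 + sum(flags[, l]); b <- 1 + sum(dts - flags[, l])
      draws <- fit$psi[, 1, l]
      expect_lt(abs(mean(draws) - a / (a + b)), 3 * mc_se(draws))
      sd_exact <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
      expect_lt(abs(sd(draws) - sd_exact),
                3 * sd_exact * sqrt(2 / length(draws)) * 5)
    }
  }
})

test_that("probability posterior means match hand-computed conjugate cases", {
  # 10 undisturbed plots, 10-year intervals: Beta(1, 101), mean 1/102
  obs <- data.frame(species_code = 1L, plot_id = paste0("P", 1:10), y = 0,
                    fire = 0L, insect = 0L, disease = 0L, delta_t = 10,
                    rd_t1 = 0.5)
  fit <- fit_probability(obs, seed = 4)
  d <- fit$psi[, 1, "fire"]
  expect_lt(abs(mean(d) - 1 / 102), 3 * mc_se(d))
  # one plot, one trial, one event: Beta(2, 1), mean 2/3
  obs1 <- obs[1, ]; obs1$fire <- 1L; obs1$delta_t <- 1
  fit1 <- fit_probability(obs1, seed = 5)
  d1 <- fit1$psi[, 1, "fire"]
  expect_lt(abs(mean(d1) - 2 / 3), 3 * mc_se(d1))
})

test_that("flat-prior severity fits agree with least squares", {
  set.seed(202)
  for (d in 1:5) {
    obs <- make_obs(n = 150, psi = runif(3, 0.02, 0.08),
                    alpha = rnorm(1, 0, 0.005),
                    beta = rnorm(3, -0.01, 0.01))
    fit <- fit_severity(obs, seed = 300 + d)
    ols <- coef(lm(y ~ fire + insect + disease, obs))
    draws <- cbind(fit$alpha[, 1], fit$beta[, 1, 1], fit$beta[, 1, 2],
                   fit$beta[, 1, 3])
    for (p in 1:4) {
      unid <- p > 1 && fit$unidentified[1, p - 1]
      if (!unid && !is.na(ols[p]))
        expect_lt(abs(mean(draws[, p]) - ols[p]),
                  3 * mc_se(draws[, p]) + 1e-6)
    }
  }
})

test_that("severity parameters are recovered from a known design", {
  set.seed(77)
  flags <- cbind(rbinom(500, 1, 0.3), 0L, 0L)
  obs <- make_obs(n = 500, alpha = 0, beta = c(-0.02, 0, 0),
                  sigma = 0.005, flags = flags)
  fit <- fit_severity(obs, seed = 9)
  b <- fit$beta[, 1, "fire"]
  expect_lt(abs(mean(b) - (-0.02)), 2 * sd(b))
  a <- fit$alpha[, 1]
  # tolerance covers both posterior spread and the sampling noise of the
  # undisturbed-plot mean the posterior concentrates on
  expect_lt(abs(mean(a) - 0), 3 * sd(a) + 0.005 / sqrt(350))
  s <- fit$sigma[, 1]
  expect_lt(abs(median(s) - 0.005), 0.002)
  expect_true(all(fit$unidentified[1, c("insect", "disease")]))
})

test_that("degenerate no-information data returns prior-dominated severities", {
  obs <- data.frame(species_code = 1L, plot_id = paste0("P", 1:20),
                    y = 0.003, fire = 0L, insect = 0L, disease = 0L,
                    delta_t = 10, rd_t1 = 0.5)
  fit <- fit_severity(obs, n_chains = 2, n_warmup = 500, n_iter = 500,
                      seed = 2)
  # intercept pinned at the common value, coefficients still at the prior
  expect_lt(abs(mean(fit$alpha[, 1]) - 0.003), 1e-3)
  expect_gt(sd(fit$beta[, 1, "fire"]), 3)
})

test_that("standardized effects are the draw-wise product scaled by baseline RD", {
  skeleton <- function(beta_val, psi_val, n = 100) {
    sev <- structure(list(
      species = 1L,
      alpha = matrix(0, n, 1), sigma = matrix(0.01, n, 1),
      beta = array(beta_val, c(n, 1, 3),
                   dimnames = list(NULL, 1L, c("fire", "insect", "disease"))),
      unidentified = matrix(FALSE, 1, 3), n_draws = n),
      class = "fsi_severity")
    pr <- structure(list(
      species = 1L,
      psi = array(psi_val, c(n, 1, 3),
                  dimnames = list(NULL, 1L, c("fire", "insect", "disease"))),
      n_draws = n), class = "fsi_probability")
    list(sev = sev, pr = pr)
  }
  sk <- skeleton(-0.01, 0.5)
  eff <- standardized_effect(sk$sev, sk$pr, c(`1` = 0.5))
  expect_equal(eff$summary$standardized, rep(-1, 3))
  expect_true(all(eff$summary$significant))

  sk0 <- skeleton(0, 0.5)
  eff0 <- standardized_effect(sk0$sev, sk0$pr, c(`1` = 0.5))
  expect_equal(eff0$summary$standardized, rep(0, 3))
  expect_false(any(eff0$summary$significant))
  expect_error(standardized_effect(sk$sev, sk$pr, c(`1` = 0)), "positive")
})

test_that("effect draws behave as an independent product", {
  set.seed(5)
  obs <- make_obs(n = 200)
  sev <- fit_severity(obs, n_chains = 2, n_warmup = 500, n_iter = 1000,
                      seed = 31)
  prob <- fit_probability(obs, n_chains = 2, n_warmup = 300, n_iter = 1000,
                          seed = 32)
  eff <- standardized_effect(sev, prob, c(`101` = 0.4))
  # zero severity implies zero effect, draw by draw
  expect_equal(sign(eff$effect[, 1, 1]),
               sign(sev$beta[, 1, 1]) * 1)
  # permuting the probability draws leaves the mean effect unchanged up to
  # Monte Carlo error (the product assumes independent posteriors)
  perm <- sample(nrow(prob$psi[, , 1, drop = FALSE]))
  for (l in 1:3) {
    e1 <- mean(sev$beta[, 1, l] * prob$psi[, 1, l])
    e2 <- mean(sev$beta[, 1, l] * prob$psi[perm, 1, l])
    tol <- 4 * sd(sev$beta[, 1, l] * prob$psi[, 1, l]) /
      sqrt(length(perm))
    expect_lt(abs(e1 - e2), tol)
  }
})
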