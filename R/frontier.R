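#' Fit the maximum size-density frontier
#'
#' Fits the self-thinning frontier `N_max(S) = a * S^r` — the upper boundary
#' of live-tree density (TPH, stems/ha) against mean tree basal area (S, m^2)
#' — as a Bayesian quantile regression of `log(TPH)` on `log(S)` at the
#' `tau = 0.99` quantile, with intercept and slope varying by forest community
#' type (random slope/intercept model). The quantile likelihood is the
#' asymmetric Laplace, sampled through its exponential scale-mixture
#' representation. Informative normal priors are placed on the population
#' intercept (`log a`: mean 7, sd 1) and slope (`r`: mean -0.8025, sd 0.1),
#' reflecting Reineke-type size-density scaling. Type deviations get
#' half-normal scale hyperpriors: scale 1 for intercepts, 0.1 for slopes
#' (cross-type variation in Reineke-type exponents is small, and a looser
#' scale lets poorly informed types drift along the quantile ridge).
#'
#' @param stands data frame of frontier-training stands with columns `tph`,
#'   `mean_tree_ba` (both positive) and `forest_type`.
#' @param tau quantile level of the frontier (default 0.99).
#' @param priors list with `intercept = c(mean, sd)` and `slope = c(mean, sd)`.
#' @param n_chains,n_adapt,n_warmup,n_iter MCMC settings; the default keeps
#'   `n_chains * n_iter = 5000` retained draws.
#' @param seed integer seed for the MCMC (one RNG stream per chain).
#' @return an object of class `"sdfrontier"`: posterior draws of per-type
#'   `log_a` and `r` (and population-level parameters), posterior-median
#'   coefficient table, and convergence diagnostics (`$diagnostics$max_rhat`,
#'   `$diagnostics$converged`). Non-convergence (split R-hat > 1.05) attaches
#'   a warning but still returns the fitted object.
#' @seealso [predict.sdfrontier()], [manual_frontier()]
#' @export
fit_frontier <- function(stands, tau = 0.99,
                         priors = list(intercept = c(7, 1),
                                       slope = c(-0.8025, 0.1)),
                         n_chains = 4, n_adapt = 1000, n_warmup = 1500,
                         n_iter = 1250, seed = 1) {
  need <- c("tph", "mean_tree_ba", "forest_type")
  stopifnot(all(need %in% names(stands)))
  stands <- stands[, need]
  if (any(!is.finite(stands$tph)) || any(!is.finite(stands$mean_tree_ba)) ||
      any(stands$tph <= 0) || any(stands$mean_tree_ba <= 0))
    stop("all tph and mean_tree_ba values must be positive and finite",
         call. = FALSE)
  types <- sort(unique(as.character(stands$forest_type)))
  type_i <- match(as.character(stands$forest_type), types)

  # Hierarchically centered random effects, sampled against the centered
  # covariate x - xbar: the intercept at the data centroid is nearly
  # orthogonal to the slope, which removes the posterior ridge that stalls
  # single-site updates of (log_a, r). The reported log_a is transformed
  # back to S = 1 (x = 0).
  model <- "
model {
  theta  <- (1 - 2 * tau) / (tau * (1 - tau))
  kappa2 <- 2 / (tau * (1 - tau))
  for (i in 1:n) {
    w[i] ~ dexp(inv_sigma)
    mu[i] <- lac[type[i]] + r[type[i]] * (x[i] - xbar)
    y[i] ~ dnorm(mu[i] + theta * w[i], inv_sigma / (kappa2 * w[i]))
  }
  for (t in 1:T) {
    lac[t] ~ dnorm(b0c, prec_u0)
    r[t] ~ dnorm(b1, prec_u1)
    log_a[t] <- lac[t] - r[t] * xbar
  }
  sd_u0 ~ dnorm(0, 1) T(0,)
  sd_u1 ~ dnorm(0, 100) T(0,)
  prec_u0 <- pow(sd_u0, -2)
  prec_u1 <- pow(sd_u1, -2)
  b0 ~ dnorm(pr_b0_mu, pr_b0_prec)
  b1 ~ dnorm(pr_b1_mu, pr_b1_prec)
  b0c <- b0 + b1 * xbar
  sigma ~ dunif(0, 10)
  inv_sigma <- 1 / sigma
}"
  data <- list(y = log(stands$tph), x = log(stands$mean_tree_ba),
               xbar = mean(log(stands$mean_tree_ba)),
               type = type_i, n = nrow(stands), T = length(types), tau = tau,
               pr_b0_mu = priors$intercept[1],
               pr_b0_prec = priors$intercept[2]^-2,
               pr_b1_mu = priors$slope[1],
               pr_b1_prec = priors$slope[2]^-2)
  inits <- lapply(seq_len(n_chains), function(ch)
    list(b0 = priors$intercept[1], b1 = priors$slope[1], sigma = 0.1,
         lac = rep(priors$intercept[1] +
                     priors$slope[1] * mean(log(stands$mean_tree_ba)),
                   length(types)),
         r = rep(priors$slope[1], length(types)),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 101 + ch) %% 2147483647))
  jm <- rjags::jags.model(textConnection(model), data = data, inits = inits,
                          n.chains = n_chains, n.adapt = n_adapt,
                          quiet = TRUE)
  stats::update(jm, n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("log_a", "r", "b0", "b1", "sd_u0",
                                    "sd_u1", "sigma"),
                              n.iter = n_iter, progress.bar = "none")
  rhat <- tryCatch(
    coda::gelman.diag(samp, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) NA_real_)
  # convergence is judged on the parameters the fitted curves use (per-type
  # log_a, r and the AL scale); population means and deviation scales are
  # weakly identified whenever few types are observed and their slow mixing
  # does not affect the per-type curves
  core <- rhat[grepl("^(log_a|r)\\[|^sigma", names(rhat))]
  max_rhat <- suppressWarnings(max(core, na.rm = TRUE))
  converged <- is.finite(max_rhat) && max_rhat <= 1.05

  draws <- as.matrix(samp)
  # JAGS drops the index from length-one vector nodes
  pick <- function(nm, alt) if (nm %in% colnames(draws)) draws[, nm] else
    draws[, alt]
  la <- sapply(seq_along(types), function(t)
    pick(sprintf("log_a[%d]", t), "log_a"))
  rr <- sapply(seq_along(types), function(t) pick(sprintf("r[%d]", t), "r"))
  la <- matrix(la, nrow(draws), length(types),
               dimnames = list(NULL, types))
  rr <- matrix(rr, nrow(draws), length(types),
               dimnames = list(NULL, types))
  coef_tab <- data.frame(
    forest_type = types,
    log_a = apply(la, 2, stats::median),
    a = exp(apply(la, 2, stats::median)),
    r = apply(rr, 2, stats::median),
    row.names = NULL, stringsAsFactors = FALSE
  )
  obj <- structure(list(
    tau = tau, types = types,
    draws = list(log_a = la, r = rr, b0 = draws[, "b0"], b1 = draws[, "b1"],
                 sd_u0 = draws[, "sd_u0"], sd_u1 = draws[, "sd_u1"],
                 sigma = draws[, "sigma"]),
    coef = coef_tab,
    population = c(log_a = stats::median(draws[, "b0"]),
                   r = stats::median(draws[, "b1"])),
    diagnostics = list(rhat = rhat, max_rhat = max_rhat,
                       converged = converged),
    n_draws = nrow(draws), n_stands = nrow(stands), priors = priors,
    call = match.call()
  ), class = "sdfrontier")
  if (any(coef_tab$r >= 0))
    warning("posterior median slope is non-negative for type(s): ",
            paste(coef_tab$forest_type[coef_tab$r >= 0], collapse = ", "),
            " (fit-quality failure)", call. = FALSE)
  if (!converged)
    warning(sprintf("MCMC may not have converged (max split R-hat = %.3f)",
                    max_rhat), call. = FALSE)
  obj
}

#' Frontier with fixed, known parameters
#'
#' Builds an `"sdfrontier"` object from given coefficients instead of an MCMC
#' fit — a degenerate posterior with a single draw. Useful for computing
#' relative densities against a published or simulated reference curve.
#'
#' @param log_a intercept(s) `log(a)`, recycled over `types`.
#' @param r negative exponent(s), recycled over `types`.
#' @param types forest-type labels; `NULL` for a single population-level
#'   curve.
#' @return an `"sdfrontier"` object.
#' @export
manual_frontier <- function(log_a, r, types = NULL) {
  if (any(r >= 0)) stop("r must be negative", call. = FALSE)
  if (is.null(types)) types <- "all"
  k <- length(types)
  log_a <- rep_len(log_a, k); r <- rep_len(r, k)
  la <- matrix(log_a, 1, k, dimnames = list(NULL, types))
  rr <- matrix(r, 1, k, dimnames = list(NULL, types))
  structure(list(
    tau = 0.99, types = types,
    draws = list(log_a = la, r = rr, b0 = mean(log_a), b1 = mean(r),
                 sd_u0 = 0, sd_u1 = 0, sigma = 0),
    coef = data.frame(forest_type = types, log_a = log_a, a = exp(log_a),
                      r = r, row.names = NULL, stringsAsFactors = FALSE),
    population = c(log_a = mean(log_a), r = mean(r)),
    diagnostics = list(rhat = NULL, max_rhat = NA_real_, converged = TRUE),
    n_draws = 1L, n_stands = 0L, priors = NULL, call = match.call()
  ), class = "sdfrontier")
}

#' Predict maximum tree density from a fitted frontier
#'
#' Evaluates `N_max(S) = a_i * S^(r_i)` at posterior-median parameters for the
#' given forest type(s). A forest type absent from the fit falls back to the
#' population-level curve; affected types are recorded in the
#' `"population_curve_types"` attribute of the result.
#'
#' @param object an `"sdfrontier"`.
#' @param s_bar tree size index (mean tree basal area, m^2), positive.
#' @param forest_type type label(s), recycled against `s_bar`; `NULL` uses
#'   the population-level curve.
#' @param ... unused.
#' @return stems/ha, same length as `s_bar`.
#' @export
predict.sdfrontier <- function(object, s_bar, forest_type = NULL, ...) {
  if (any(!is.finite(s_bar)) || any(s_bar <= 0))
    stop("s_bar must be positive", call. = FALSE)
  if (is.null(forest_type)) {
    out <- exp(object$population["log_a"] + object$population["r"] *
                 log(s_bar))
    return(unname(out))
  }
  forest_type <- rep_len(as.character(forest_type), length(s_bar))
  i <- match(forest_type, object$coef$forest_type)
  la <- ifelse(is.na(i), object$population["log_a"], object$coef$log_a[i])
  r <- ifelse(is.na(i), object$population["r"], object$coef$r[i])
  out <- exp(la + r * log(s_bar))
  unknown <- unique(forest_type[is.na(i)])
  if (length(unknown))
    attr(out, "population_curve_types") <- unknown
  out
}

#' @export
coef.sdfrontier <- function(object, ...) object$coef

#' @export
print.sdfrontier <- function(x, ...) {
  cat(sprintf("Maximum size-density frontier (tau = %.2f, %d draws, %d stands)\n",
              x$tau, x$n_draws, x$n_stands))
  print(x$coef, digits = 4)
  if (!is.na(x$diagnostics$max_rhat))
    cat(sprintf("max split R-hat: %.3f (%s)\n", x$diagnostics$max_rhat,
                if (x$diagnostics$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.sdfrontier <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  qs <- function(m) t(apply(m, 2, stats::quantile, probs = probs))
  la <- as.data.frame(qs(object$draws$log_a))
  rr <- as.data.frame(qs(object$draws$r))
  names(la) <- names(rr) <- paste0("q", probs * 100)
  la$parameter <- "log_a"; rr$parameter <- "r"
  la$forest_type <- rr$forest_type <- object$types
  res <- rbind(la, rr)[, c("parameter", "forest_type",
                           paste0("q", probs * 100))]
  rownames(res) <- NULL
  structure(list(table = res, diagnostics = object$diagnostics,
                 tau = object$tau), class = "summary.sdfrontier")
}

#' @export
print.summary.sdfrontier <- function(x, ...) {
  cat(sprintf("Posterior quantiles of frontier parameters (tau = %.2f)\n",
              x$tau))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
plot.sdfrontier <- function(x, stands = NULL, ...) {
  cf <- x$coef
  if (!is.null(stands)) {
    graphics::plot(log(stands$mean_tree_ba), log(stands$tph),
                   pch = 16, cex = 0.4, col = "grey50",
                   xlab = "log mean tree basal area (m^2)",
                   ylab = "log TPH (stems/ha)", ...)
  } else {
    graphics::plot(NULL, xlim = c(-6, 0), ylim = c(2, 12),
                   xlab = "log mean tree basal area (m^2)",
                   ylab = "log TPH (stems/ha)", ...)
  }
  for (i in seq_len(nrow(cf)))
    graphics::abline(cf$log_a[i], cf$r[i], col = i + 1, lwd = 2)
  graphics::legend("topright", legend = cf$forest_type,
                   col = seq_len(nrow(cf)) + 1, lwd = 2, bty = "n")
  invisible(x)
}
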