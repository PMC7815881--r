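#' Configuration for a synthetic inventory landscape
#'
#' Defines the generating conditions of a synthetic remeasured-inventory
#' landscape with known ground truth: a power-law size-density frontier per
#' forest type, stands placed below (or, with the exceedance probability, at
#' or above) the frontier, paired censuses roughly a decade apart within a
#' 2001-2018 study window, annual Bernoulli disturbance processes summarized
#' as binary interval flags, additive per-year disturbance severities on
#' relative density, and post-stratification labels. Defaults mirror a
#' western-US style inventory: mean remeasurement interval 9.78 years,
#' remeasurement years 2011-2018, frontier `log a = 7`, `r = -0.8`, 1%
#' exceedance.
#'
#' @param n_plots number of remeasured plots.
#' @param n_forest_types number of forest community types.
#' @param log_a,r true frontier parameters, recycled over types (`r < 0`).
#' @param exceedance fraction of stands at or above the frontier (in (0,1));
#'   the frontier is exactly the `1 - exceedance` quantile of TPH given size.
#' @param species integer species codes.
#' @param species_weights `n_forest_types x length(species)` matrix of mixing
#'   weights (rows normalized); default concentrates a dominant species per
#'   type.
#' @param delta_t_mean,delta_t_sd remeasurement interval distribution, years.
#' @param study_years calendar range of all measurements.
#' @param remeasure_years calendar years of second censuses (annual panels).
#' @param psi annual disturbance probability, `length(species) x 3` matrix
#'   (columns fire, insect, disease).
#' @param beta disturbance severity: additive shift of a species' FSI
#'   (RD/year) on disturbed plots, `length(species) x 3` matrix.
#' @param drift mean undisturbed annual change in relative density, per
#'   species (recycled).
#' @param noise_sd plot-level FSI noise standard deviation (RD/year).
#' @param skew_mode `"normal"` for near-symmetric diameter distributions that
#'   pass the skewness screen, `"skewed"` for right-skewed ones that fail it.
#' @param n_subsections,n_strata numbers of ecoregion subsections (grouped
#'   into two divisions) and post-stratification strata.
#' @param range_map optional named list: species code -> subsection labels
#'   the species is allowed to occur in (default: everywhere).
#' @param seed integer seed (mandatory; every plot uses a substream keyed by
#'   its index).
#' @return validated object of class `"landscape_config"`.
#' @export
landscape_config <- function(n_plots = 1000, n_forest_types = 3,
                             log_a = 7, r = -0.8, exceedance = 0.01,
                             species = c(101L, 202L, 303L),
                             species_weights = NULL,
                             delta_t_mean = 9.78, delta_t_sd = 0.7,
                             study_years = c(2001, 2018),
                             remeasure_years = 2011:2018,
                             psi = NULL, beta = NULL, drift = 0,
                             noise_sd = 0.005,
                             skew_mode = c("normal", "skewed"),
                             n_subsections = 5, n_strata = 4,
                             range_map = NULL, seed) {
  skew_mode <- match.arg(skew_mode)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  J <- length(species); Ty <- n_forest_types
  log_a <- rep_len(log_a, Ty); r <- rep_len(r, Ty)
  if (any(r >= 0)) stop("r must be negative", call. = FALSE)
  if (!(exceedance > 0 && exceedance < 1))
    stop("exceedance must be in (0, 1)", call. = FALSE)
  if (is.null(species_weights)) {
    species_weights <- matrix(0.2 / max(1, J - 1), Ty, J)
    for (t in seq_len(Ty))
      species_weights[t, 1 + (t - 1) %% J] <- 0.8
    if (J == 1) species_weights[] <- 1
  }
  species_weights <- species_weights / rowSums(species_weights)
  if (is.null(psi)) psi <- matrix(0, J, 3)
  if (is.null(beta)) beta <- matrix(0, J, 3)
  psi <- matrix(psi, J, 3); beta <- matrix(beta, J, 3)
  if (any(psi < 0 | psi > 1)) stop("psi must be in [0, 1]", call. = FALSE)
  colnames(psi) <- colnames(beta) <- c("fire", "insect", "disease")
  drift <- rep_len(drift, J)
  structure(list(
    n_plots = n_plots, n_forest_types = Ty, log_a = log_a, r = r,
    exceedance = exceedance, species = species,
    species_weights = species_weights, delta_t_mean = delta_t_mean,
    delta_t_sd = delta_t_sd, study_years = study_years,
    remeasure_years = remeasure_years, psi = psi, beta = beta,
    drift = drift, noise_sd = noise_sd, skew_mode = skew_mode,
    n_subsections = n_subsections, n_strata = n_strata,
    range_map = range_map, seed = as.integer(seed)
  ), class = "landscape_config")
}

# Distribution of total stand relative density: Beta(3, 2) rescaled so that
# its 1 - exceedance quantile is exactly 1 (the frontier). Mass concentrates
# at 0.5-0.9 of maximum density — undisturbed even-aged stands accumulate
# near the self-thinning frontier, giving the crisp upper boundary an
# extreme-quantile frontier fit requires.
.rd_shape1 <- 3
.rd_shape2 <- 2
.rd_scale <- function(exceedance)
  stats::qbeta(1 - exceedance, .rd_shape1, .rd_shape2)

#' Expected baseline relative density per species under a config
#'
#' Closed-form expectation of a species' plot-level relative density at the
#' first census: the species' average mixing weight across forest types times
#' the mean of the total-stand relative density distribution (a lognormal
#' rescaled so its upper `1 - exceedance` quantile is the frontier). Useful
#' for setting drifts or severities that target a known percent change rate.
#' Ignores any `range_map` restriction.
#'
#' @param config a `"landscape_config"`.
#' @return named numeric vector, one entry per species code.
#' @export
expected_baseline_rd <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  e_tot <- (.rd_shape1 / (.rd_shape1 + .rd_shape2)) /
    .rd_scale(config$exceedance)
  stats::setNames(colMeans(config$species_weights) * e_tot,
                  config$species)
}

#' Points along a self-thinning track
#'
#' Returns stands lying exactly on the frontier `N = a * S^r` at
#' geometrically spaced mean tree sizes — the trajectory of an even-aged
#' stand under self-thinning, along which relative density is constant
#' (FSI = 0).
#'
#' @param a scaling factor (> 0), stems/ha at `S = 1`.
#' @param r negative exponent.
#' @param start_s,end_s mean tree basal area range, `0 < start_s < end_s`.
#' @param steps number of points.
#' @return data frame with `s_bar` and `tph`.
#' @export
simulate_self_thinning_track <- function(a, r, start_s, end_s, steps = 10) {
  if (a <= 0) stop("a must be positive", call. = FALSE)
  if (r >= 0) stop("r must be negative", call. = FALSE)
  if (!(start_s > 0 && end_s > start_s))
    stop("need 0 < start_s < end_s", call. = FALSE)
  s <- exp(seq(log(start_s), log(end_s), length.out = steps))
  data.frame(s_bar = s, tph = a * s^r)
}

# lognormal sdlog of the DBH family by diameter-distribution shape
.skew_sdlog <- c(normal = 0.12, skewed = 0.8)

.draw_tree_list <- function(n, tph, s_bar, sdlog) {
  dbh <- stats::rlnorm(n, meanlog = log(25), sdlog = sdlog)
  # rescale so the realized mean tree basal area matches s_bar exactly
  # (scaling leaves the DBH skewness unchanged)
  dbh <- dbh * sqrt(s_bar / mean(basal_area(dbh)))
  dbh <- pmax(dbh, 2.6)  # all stems above the 2.54 cm threshold
  list(dbh = dbh, density_factor = rep(tph / n, n))
}

#' Generate a synthetic remeasured inventory with known ground truth
#'
#' Draws a landscape of paired plot censuses under a [landscape_config()].
#' For each plot: a forest type, a mean tree size, and a total relative
#' density whose `1 - exceedance` quantile sits exactly on the type's true
#' frontier determine the initial stand; a tree list is drawn from a
#' lognormal diameter family moment-matched to the stand's size index, with
#' species drawn from the type's mixing weights (restricted to the species'
#' allowed subsections). The second census applies, per species, annual drift
#' plus additive disturbance severities (flags set when at least one annual
#' Bernoulli event occurs in the interval) plus Gaussian noise to relative
#' density, truncated at zero, and rescales the species' expansion factors
#' accordingly. Identical config and seed give byte-identical output.
#'
#' @param config a `"landscape_config"`.
#' @return list of class `"fsi_landscape"`: `inventory` (an
#'   `"fsi_inventory"`), `scheme` (stratification data frame with `stratum_id`
#'   and weight `W`), and `truth` (generating parameters plus per-plot truth:
#'   type, sizes, per-species RD at both censuses, disturbance flags and
#'   event counts, realized FSI).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  cf <- config
  J <- length(cf$species); Ty <- cf$n_forest_types
  scale <- .rd_scale(cf$exceedance)
  sdlog <- .skew_sdlog[[cf$skew_mode]]
  subsections <- sprintf("SUB%02d", seq_len(cf$n_subsections))
  divisions <- ifelse(seq_len(cf$n_subsections) <=
                        ceiling(cf$n_subsections / 2), "DIV1", "DIV2")
  W <- seq_len(cf$n_strata); W <- W / sum(W)
  strata <- sprintf("STR%02d", seq_len(cf$n_strata))

  plots <- vector("list", 2L * cf$n_plots)
  trees <- vector("list", 2L * cf$n_plots)
  truth_rows <- vector("list", cf$n_plots)

  for (k in seq_len(cf$n_plots)) {
    set.seed((cf$seed + 7919 * k) %% 2147483647)
    type <- sample.int(Ty, 1)
    sub_i <- sample.int(cf$n_subsections, 1)
    stratum <- sample(strata, 1, prob = W)
    t2 <- cf$remeasure_years[sample.int(length(cf$remeasure_years), 1)]
    dt_max <- t2 - cf$study_years[1]
    delta_t <- min(dt_max, max(5, round(stats::rnorm(1, cf$delta_t_mean,
                                                     cf$delta_t_sd))))
    t1 <- t2 - delta_t

    s_bar <- stats::rlnorm(1, -3.5, 0.7)
    rd_tot <- stats::rbeta(1, .rd_shape1, .rd_shape2) / scale
    tph <- rd_tot * exp(cf$log_a[type]) * s_bar^cf$r[type]
    n_trees <- max(3L, min(60L, as.integer(round(tph * 0.0672))))

    w <- cf$species_weights[type, ]
    if (!is.null(cf$range_map)) {
      allowed <- vapply(as.character(cf$species), function(sp) {
        rm <- cf$range_map[[sp]]
        is.null(rm) || subsections[sub_i] %in% rm
      }, logical(1))
      w <- w * allowed
      if (all(w == 0)) w <- allowed / sum(allowed)
    }
    sp <- cf$species[sample.int(J, n_trees, replace = TRUE, prob = w)]
    tl <- .draw_tree_list(n_trees, tph, s_bar, sdlog)

    # true tree-level relative densities against the type's own frontier
    nmax <- exp(cf$log_a[type]) * basal_area(tl$dbh)^cf$r[type]
    rd_tree <- tl$density_factor / nmax
    rd_sp_t1 <- vapply(cf$species, function(s)
      sum(rd_tree[sp == s]), numeric(1))

    # disturbance: annual Bernoulli events at the dominant species' rates
    dom <- which.max(cf$species_weights[type, ])
    events <- vapply(1:3, function(l)
      stats::rbinom(1, delta_t, cf$psi[dom, l]), integer(1))
    x <- as.integer(events > 0)

    eps <- stats::rnorm(J, 0, cf$noise_sd)
    fsi_true <- cf$drift + as.vector(cf$beta %*% x) + eps
    rd_sp_t2 <- pmax(0, rd_sp_t1 + delta_t * fsi_true)
    ratio <- ifelse(rd_sp_t1 > 0, rd_sp_t2 / rd_sp_t1, 0)

    id1 <- sprintf("P%05d_1", k); id2 <- sprintf("P%05d_2", k)
    mk_plot <- function(id, prev, year, xfl) data.frame(
      plot_id = id, prev_plot_id = prev, census_year = year,
      forest_type = sprintf("FT%02d", type), site_class = 1L + (k %% 7L),
      ecoregion_division = divisions[sub_i],
      ecoregion_subsection = subsections[sub_i], stratum_id = stratum,
      fire = xfl[1], insect = xfl[2], disease = xfl[3],
      other_disturbance = 0L, treated = 0L, treatment_year = NA_real_,
      stringsAsFactors = FALSE)
    plots[[2 * k - 1]] <- mk_plot(id1, NA_character_, t1, c(0L, 0L, 0L))
    plots[[2 * k]] <- mk_plot(id2, id1, t2, x)

    mk_trees <- function(id, df) data.frame(
      plot_id = id, tree_id = paste0(id, "_T", seq_len(n_trees)),
      species_code = sp, dbh = tl$dbh, status = "live",
      density_factor = df, basal_area = basal_area(tl$dbh),
      stringsAsFactors = FALSE)
    trees[[2 * k - 1]] <- mk_trees(id1, tl$density_factor)
    df2 <- tl$density_factor * ratio[match(sp, cf$species)]
    tr2 <- mk_trees(id2, df2)
    trees[[2 * k]] <- tr2[tr2$density_factor > 0, , drop = FALSE]

    truth_rows[[k]] <- data.frame(
      plot = k, plot_id_t2 = id2, forest_type = sprintf("FT%02d", type),
      s_bar = s_bar, rd_total_t1 = rd_tot, tph_t1 = tph,
      delta_t = delta_t, panel = t2,
      species_code = cf$species, rd_t1 = rd_sp_t1, rd_t2 = rd_sp_t2,
      fsi_applied = fsi_true,
      fsi_realized = (rd_sp_t2 - rd_sp_t1) / delta_t,
      fire = x[1], insect = x[2], disease = x[3],
      events_fire = events[1], events_insect = events[2],
      events_disease = events[3],
      dominant_species = cf$species[dom],
      stringsAsFactors = FALSE)
  }

  inv <- structure(list(plots = do.call(rbind, plots),
                        trees = do.call(rbind, trees)),
                   class = "fsi_inventory")
  inv$plots$paired <- !is.na(inv$plots$prev_plot_id)
  idx <- match(inv$plots$prev_plot_id, inv$plots$plot_id)
  inv$plots$prev_year <- ifelse(inv$plots$paired,
                                inv$plots$census_year[idx], NA_real_)
  inv$plots$delta_t <- inv$plots$census_year - inv$plots$prev_year
  rownames(inv$plots) <- rownames(inv$trees) <- NULL

  structure(list(
    inventory = inv,
    scheme = data.frame(stratum_id = strata, W = W,
                        stringsAsFactors = FALSE),
    truth = list(config = cf, plots = do.call(rbind, truth_rows),
                 frontier = data.frame(
                   forest_type = sprintf("FT%02d", seq_len(Ty)),
                   log_a = cf$log_a, r = cf$r, stringsAsFactors = FALSE))
  ), class = "fsi_landscape")
}

#' @export
print.fsi_landscape <- function(x, ...) {
  cat("Synthetic landscape:", nrow(x$truth$plots) /
        length(x$truth$config$species), "plots,",
      length(x$truth$config$species), "species,",
      x$truth$config$n_forest_types, "forest types\n")
  invisible(x)
}
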