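#' Post-stratification scheme
#'
#' @param stratum_id stratum labels.
#' @param weight known proportion of area in each stratum (must sum to 1).
#' @return data frame of class `"stratification_scheme"`.
#' @export
stratification_scheme <- function(stratum_id, weight) {
  if (abs(sum(weight) - 1) > 1e-8)
    stop("stratum weights must sum to 1", call. = FALSE)
  structure(data.frame(stratum_id = as.character(stratum_id), W = weight,
                       stringsAsFactors = FALSE),
            class = c("stratification_scheme", "data.frame"))
}

# Post-stratified moments of one or more plot-level variables.
# Y: n x p matrix. Returns list(mean = p-vector, cov = p x p matrix of the
# covariance of the estimated means, n = n, collapsed = logical).
# Stratum weights are renormalized over strata with sampled plots; strata
# with a single plot are merged into the largest-weight sampled stratum.
.ps_moments <- function(Y, stratum, scheme) {
  Y <- as.matrix(Y)
  stratum <- as.character(stratum)
  unknown <- setdiff(unique(stratum), scheme$stratum_id)
  if (length(unknown))
    stop("plots in unknown stratum(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sc <- scheme[scheme$stratum_id %in% stratum, , drop = FALSE]
  sc$W <- sc$W / sum(sc$W)
  collapsed <- FALSE
  repeat {
    ns <- table(factor(stratum, levels = sc$stratum_id))
    singles <- names(ns)[ns == 1]
    if (!length(singles) || nrow(sc) == 1) break
    s <- singles[1]
    others <- sc$stratum_id[sc$stratum_id != s]
    target <- others[which.max(sc$W[sc$stratum_id != s])]
    stratum[stratum == s] <- target
    sc$W[sc$stratum_id == target] <- sc$W[sc$stratum_id == target] +
      sc$W[sc$stratum_id == s]
    sc <- sc[sc$stratum_id != s, , drop = FALSE]
    collapsed <- TRUE
  }
  p <- ncol(Y)
  mean_v <- numeric(p)
  cov_m <- matrix(0, p, p)
  for (i in seq_len(nrow(sc))) {
    rows <- stratum == sc$stratum_id[i]
    n_s <- sum(rows)
    ybar <- colMeans(Y[rows, , drop = FALSE])
    mean_v <- mean_v + sc$W[i] * ybar
    if (n_s >= 2) {
      S <- stats::cov(Y[rows, , drop = FALSE])
      cov_m <- cov_m + sc$W[i]^2 * S / n_s
    } else {
      cov_m[] <- NA_real_
    }
  }
  list(mean = mean_v, cov = cov_m, n = nrow(Y), collapsed = collapsed)
}

#' Post-stratified mean and variance of a plot-level variable
#'
#' The standard post-stratified estimators: `mean = sum_s W_s * ybar_s` and
#' `variance = sum_s W_s^2 * s_s^2 / n_s`, with stratum weights renormalized
#' over sampled strata. Strata containing a single plot are collapsed into
#' the largest-weight sampled stratum before variance computation (flagged in
#' the result). With a single stratum this reduces exactly to the sample mean
#' and `s^2 / n`.
#'
#' @param y plot-level values.
#' @param stratum stratum label per plot (must appear in `scheme`).
#' @param scheme a [stratification_scheme()].
#' @return list with `mean`, `variance`, `n`, `collapsed`.
#' @export
poststratified_estimate <- function(y, stratum, scheme) {
  m <- .ps_moments(cbind(y), stratum, scheme)
  list(mean = unname(m$mean[1]), variance = unname(m$cov[1, 1]), n = m$n,
       collapsed = m$collapsed)
}

.classify <- function(lo, hi) {
  if (is.na(lo) || is.na(hi)) return(NA_character_)
  if (hi < 0) "declining" else if (lo > 0) "expanding" else "stable"
}

#' Combine annual-panel estimates with a simple moving average
#'
#' Panels (mutually exclusive sets of plots remeasured in the same year) are
#' combined with equal weight irrespective of time since remeasurement:
#' `mean = mean(panel means)`, `variance = sum(panel variances) / P^2`. The
#' 95% confidence interval is normal-theory (`mean +/- 1.96 * sqrt(var)`),
#' and the population is classified `declining` when the interval lies below
#' zero, `expanding` when above, and `stable` when it contains zero.
#'
#' @param panel_estimates data frame with columns `mean` and `variance`, one
#'   row per panel.
#' @return list with `mean`, `variance`, `ci95` (length-2), `classification`,
#'   `panels_used`.
#' @export
moving_average_panels <- function(panel_estimates) {
  if (is.null(nrow(panel_estimates)) || nrow(panel_estimates) == 0)
    stop("at least one panel is required", call. = FALSE)
  P <- nrow(panel_estimates)
  m <- mean(panel_estimates$mean)
  v <- sum(panel_estimates$variance) / P^2
  ci <- m + c(-1, 1) * 1.96 * sqrt(v)
  list(mean = m, variance = v, ci95 = ci,
       classification = .classify(ci[1], ci[2]), panels_used = P)
}

#' Species ranges from plot-level detections
#'
#' A species' range is the set of ecoregion subsections where it was detected
#' on at least one plot at either census.
#'
#' @param records change records ([population_change()] output), or any data
#'   frame with `species_code`, `ecoregion_subsection`, `rd_t1`, `rd_t2`.
#' @return named list: species code -> character vector of subsections.
#' @export
define_range <- function(records) {
  detected <- records[records$rd_t1 > 0 | records$rd_t2 > 0, , drop = FALSE]
  lapply(split(detected$ecoregion_subsection, detected$species_code),
         function(s) sort(unique(s)))
}

#' Population-level estimates of change in relative density
#'
#' For each requested population (species, optionally crossed with size class
#' and/or ecoregion unit), estimates the range-average FSI by post-stratified
#' estimation within each annual panel and equal-weight combination across
#' panels, classifies the population (expanding / declining / stable by
#' whether the 95% CI excludes zero), and reports the percent FSI as a ratio
#' of means (mean FSI over mean baseline RD) with a first-order delta-method
#' standard error that accounts for the plot-level covariance of the two
#' means. Plots inside a species' range with no stems of the species at
#' either census contribute zeros. Panels with fewer than two plots are
#' dropped (counted in `panels_used`).
#'
#' @param records output of [population_change()].
#' @param plots the eligible pairs (e.g. `filter_change_analysis(inv)$kept`):
#'   the plot universe with `plot_id`, `stratum_id`, `ecoregion_subsection`,
#'   `ecoregion_division`, `census_year`.
#' @param scheme a [stratification_scheme()].
#' @param by grouping columns beyond species: any of `"size_class"`,
#'   `"ecoregion_division"`, `"ecoregion_subsection"`.
#' @param species species codes to estimate (default: all in `records`).
#' @return data frame with one row per group: grouping keys, `mean_fsi`,
#'   `variance`, `se`, `lo95`, `hi95`, `classification`, `mean_rd_t1`,
#'   `percent_fsi`, `percent_fsi_se`, `n_plots`, `panels_used`. Deterministic
#'   ordering by the grouping keys.
#' @export
grouped_estimates <- function(records, plots, scheme, by = character(0),
                              species = NULL) {
  stopifnot(all(by %in% c("size_class", "ecoregion_division",
                          "ecoregion_subsection")))
  if ("size_class" %in% by && !"size_class" %in% names(records))
    stop("records carry no size classes; run population_change(by_size_class = TRUE)",
         call. = FALSE)
  if (is.null(species)) species <- sort(unique(records$species_code))
  ranges <- define_range(records)
  never <- setdiff(as.character(species), names(ranges))
  if (length(never))
    stop("species never detected: ", paste(never, collapse = ", "),
         call. = FALSE)
  plots$panel <- plots$census_year

  groups <- list()
  for (sp in species) {
    in_range <- plots[plots$ecoregion_subsection %in%
                        ranges[[as.character(sp)]], , drop = FALSE]
    sp_rec <- records[records$species_code == sp, , drop = FALSE]
    keys <- expand.grid(
      size_class = if ("size_class" %in% by)
        sort(unique(sp_rec$size_class)) else NA,
      ecoregion_division = if ("ecoregion_division" %in% by)
        sort(unique(in_range$ecoregion_division)) else NA,
      ecoregion_subsection = if ("ecoregion_subsection" %in% by)
        sort(unique(in_range$ecoregion_subsection)) else NA,
      stringsAsFactors = FALSE)
    for (g in seq_len(nrow(keys))) {
      univ <- in_range
      rec <- sp_rec
      if (!is.na(keys$ecoregion_division[g])) {
        univ <- univ[univ$ecoregion_division ==
                       keys$ecoregion_division[g], , drop = FALSE]
      }
      if (!is.na(keys$ecoregion_subsection[g])) {
        univ <- univ[univ$ecoregion_subsection ==
                       keys$ecoregion_subsection[g], , drop = FALSE]
      }
      if (!is.na(keys$size_class[g]))
        rec <- rec[rec$size_class == keys$size_class[g], , drop = FALSE]
      if (nrow(univ) == 0) next
      i <- match(univ$plot_id, rec$plot_id)
      y <- ifelse(is.na(i), 0, rec$fsi[i])
      rd1 <- ifelse(is.na(i), 0, rec$rd_t1[i])

      panel_rows <- split(seq_len(nrow(univ)), univ$panel)
      pm <- lapply(panel_rows, function(rows) {
        if (length(rows) < 2) return(NULL)
        .ps_moments(cbind(fsi = y[rows], rd1 = rd1[rows]),
                    univ$stratum_id[rows], scheme)
      })
      pm <- pm[!vapply(pm, is.null, logical(1))]
      if (!length(pm)) next
      P <- length(pm)
      mean_fsi <- mean(vapply(pm, function(m) m$mean[1], numeric(1)))
      mean_rd1 <- mean(vapply(pm, function(m) m$mean[2], numeric(1)))
      cov_comb <- Reduce(`+`, lapply(pm, `[[`, "cov")) / P^2
      v <- cov_comb[1, 1]
      ci <- mean_fsi + c(-1, 1) * 1.96 * sqrt(v)
      if (mean_rd1 > 0) {
        pf <- percent_fsi(mean_fsi, mean_rd1)
        # first-order delta method for the ratio of two correlated means
        gvec <- c(100 / mean_rd1, -100 * mean_fsi / mean_rd1^2)
        pf_se <- sqrt(drop(t(gvec) %*% cov_comb %*% gvec))
      } else {
        pf <- NA_real_; pf_se <- NA_real_
      }
      groups[[length(groups) + 1]] <- data.frame(
        species_code = sp,
        size_class = keys$size_class[g],
        ecoregion_division = keys$ecoregion_division[g],
        ecoregion_subsection = keys$ecoregion_subsection[g],
        mean_fsi = mean_fsi, variance = v, se = sqrt(v),
        lo95 = ci[1], hi95 = ci[2],
        classification = .classify(ci[1], ci[2]),
        mean_rd_t1 = mean_rd1, percent_fsi = pf, percent_fsi_se = pf_se,
        n_plots = sum(vapply(pm, `[[`, 0, "n")), panels_used = P,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, groups)
  if (is.null(out)) stop("no estimable groups", call. = FALSE)
  drop_cols <- setdiff(c("size_class", "ecoregion_division",
                         "ecoregion_subsection"), by)
  out <- out[, setdiff(names(out), drop_cols), drop = FALSE]
  ord <- do.call(order, out[, c("species_code", by), drop = FALSE])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
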