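#' Tree-level relative density of a population
#'
#' Relative density (RD) of a population of trees in one census is the sum of
#' tree-level relative densities: each tree contributes its represented
#' density divided by the maximum density attainable in a stand whose average
#' tree size equals that tree's own size,
#' `RD = sum_h N_h / N_max(S_h)`. Summing tree by tree avoids the class
#' aggregation bias of the aggregate index `TPH / N_max(mean S)` in stands
#' with non-normal size distributions, and makes RD exactly additive over any
#' partition of the tree list (e.g. size classes). RD is not capped at 1: the
#' frontier is a 99th percentile, so a small fraction of stands legitimately
#' exceed it.
#'
#' @param trees data frame with columns `density_factor` (stems/ha) and
#'   `basal_area` (m^2; computed from `dbh` if absent). Pass only live stems
#'   with DBH >= 2.54 cm.
#' @param model an `"sdfrontier"`.
#' @param forest_type single forest-type label of the stand.
#' @return dimensionless RD (>= 0; 0 for an empty tree list).
#' @export
relative_density <- function(trees, model, forest_type = NULL) {
  if (is.null(trees) || nrow(trees) == 0) return(0)
  ba <- if ("basal_area" %in% names(trees)) trees$basal_area else
    basal_area(trees$dbh)
  nmax <- predict(model, s_bar = ba,
                  forest_type = if (is.null(forest_type)) NULL else
                    rep(forest_type, length(ba)))
  sum(trees$density_factor / nmax)
}

#' Forest stability index
#'
#' Average annual change in relative density between two successive censuses:
#' `FSI = (RD_t2 - RD_t1) / delta_t`. Positive values indicate population
#' expansion, negative values decline; range expansion from absence
#' (`rd_t1 = 0`) appears as a positive FSI.
#'
#' @param rd_t1,rd_t2 relative densities at the first and second census.
#' @param delta_t years between censuses, > 0.
#' @return FSI in units of relative density per year (vectorized).
#' @export
fsi <- function(rd_t1, rd_t2, delta_t) {
  if (any(delta_t <= 0)) stop("delta_t must be positive", call. = FALSE)
  (rd_t2 - rd_t1) / delta_t
}

#' Percent forest stability index
#'
#' Annual percent change in relative density of a population:
#' `%FSI = 100 * FSI / RD_t1`, computed at the population level as a ratio of
#' means (mean FSI over mean baseline RD), never plot by plot — baseline RD
#' of zero occurs by design on individual plots (range expansion). The total
#' change over a study period is linear: `%FSI * study_years` (a %FSI of
#' -5.56%/yr over 18 years is complete loss).
#'
#' @param mean_fsi population mean FSI (per year).
#' @param mean_rd_t1 population mean baseline relative density, > 0.
#' @return percent per year.
#' @export
percent_fsi <- function(mean_fsi, mean_rd_t1) {
  if (any(mean_rd_t1 <= 0))
    stop("mean baseline relative density must be positive (population absent at baseline)",
         call. = FALSE)
  100 * mean_fsi / mean_rd_t1
}

#' Decile size-class table from observed diameters
#'
#' Computes the nine interior decile boundaries of the observed DBH
#' distribution of each species within each site productivity class (raw
#' sample quantiles of the initial-census diameters, unweighted), plus a
#' species-level fallback row used when a species x productivity combination
#' is missing. Classes are half-open: class k covers `[q_{k-1}, q_k)`, with
#' everything at or above the 9th decile in class 10.
#'
#' @param trees initial-census tree data frame with `species_code` and `dbh`.
#' @param site_class integer site productivity class per tree (recycled).
#' @return data frame of class `"size_class_table"`: `species_code`,
#'   `site_class` (`NA` for the species-level fallback rows), `q1`..`q9`.
#' @export
size_class_table <- function(trees, site_class = NA_integer_) {
  stopifnot(all(c("species_code", "dbh") %in% names(trees)))
  site_class <- rep_len(site_class, nrow(trees))
  qrow <- function(d) stats::quantile(d, probs = seq(0.1, 0.9, 0.1),
                                      names = FALSE, type = 7)
  groups <- split(trees$dbh, list(sp = trees$species_code, sc = site_class),
                  drop = TRUE)
  per <- do.call(rbind, lapply(names(groups), function(g) {
    key <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(species_code = as.integer(key[1]),
               site_class = as.integer(key[2]),
               t(qrow(groups[[g]])))
  }))
  fallback <- do.call(rbind, lapply(split(trees$dbh, trees$species_code),
                                    function(d) data.frame(t(qrow(d)))))
  fallback <- cbind(species_code = as.integer(rownames(fallback)),
                    site_class = NA_integer_, fallback)
  out <- rbind(per, fallback)
  names(out)[3:11] <- paste0("q", 1:9)
  rownames(out) <- NULL
  class(out) <- c("size_class_table", "data.frame")
  out
}

#' Assign trees to diameter size classes
#'
#' Maps each tree to its species-and-productivity decile class 1-10 from a
#' [size_class_table()]. A species x productivity combination absent from the
#' table falls back to the species-level deciles; affected species are listed
#' in the `"fallback_species"` attribute.
#'
#' @param trees tree data frame with `species_code` and `dbh`.
#' @param table a `"size_class_table"`.
#' @param site_class integer site productivity class per tree (recycled).
#' @return integer vector of classes 1-10.
#' @export
assign_size_classes <- function(trees, table, site_class = NA_integer_) {
  site_class <- rep_len(site_class, nrow(trees))
  key <- paste(trees$species_code, site_class)
  tkey <- paste(table$species_code, table$site_class)
  i <- match(key, tkey)
  fb <- is.na(i)
  i[fb] <- match(paste(trees$species_code[fb], NA), tkey)
  if (any(is.na(i)))
    stop("species missing from size-class table: ",
         paste(unique(trees$species_code[is.na(i)]), collapse = ", "),
         call. = FALSE)
  qs <- as.matrix(table[, paste0("q", 1:9)])
  cls <- vapply(seq_along(i), function(k)
    1L + sum(trees$dbh[k] >= qs[i[k], ]), integer(1))
  if (any(fb))
    attr(cls, "fallback_species") <-
      sort(unique(trees$species_code[fb & !is.na(site_class)]))
  cls
}

#' Per-plot, per-population change in relative density
#'
#' Builds the change-analysis records: for every eligible census pair and
#' every population (species, optionally crossed with diameter size class)
#' present at either census, the relative density at both censuses and the
#' resulting FSI. A population absent from one census contributes RD = 0 on
#' that side, so colonization and local extirpation are ordinary records.
#'
#' @param inventory an `"fsi_inventory"`.
#' @param model an `"sdfrontier"` used for `N_max`.
#' @param by_size_class if `TRUE`, populations are species x size-class
#'   deciles; the decile table is built from the initial-census diameters
#'   (species within site productivity class).
#' @param sc_table optional pre-built [size_class_table()]; built from the
#'   initial censuses when `NULL` and `by_size_class = TRUE`.
#' @return data frame with one row per (plot pair, population): `plot_id`
#'   (the second census), `species_code`, optional `size_class`, `rd_t1`,
#'   `rd_t2`, `delta_t`, `fsi`, plus the pair's stratum, ecoregion labels,
#'   forest type, disturbance flags and `panel` (remeasurement year).
#' @export
population_change <- function(inventory, model, by_size_class = FALSE,
                              sc_table = NULL) {
  pairs <- filter_change_analysis(inventory)$kept
  p <- inventory$plots
  tr <- inventory$trees
  tr <- tr[tr$status == "live" & tr$dbh >= 2.54, , drop = FALSE]

  if (by_size_class && is.null(sc_table)) {
    t1_ids <- pairs$prev_plot_id
    t1_trees <- tr[tr$plot_id %in% t1_ids, , drop = FALSE]
    sc <- p$site_class[match(t1_trees$plot_id, p$plot_id)]
    sc_table <- size_class_table(t1_trees, sc)
  }

  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    t2row <- pairs[k, ]
    tr1 <- tr[tr$plot_id == t2row$prev_plot_id, , drop = FALSE]
    tr2 <- tr[tr$plot_id == t2row$plot_id, , drop = FALSE]
    ft <- t2row$forest_type
    keyify <- function(d) {
      if (!nrow(d)) return(character(0))
      if (by_size_class)
        paste(d$species_code,
              assign_size_classes(d, sc_table, t2row$site_class), sep = "|")
      else as.character(d$species_code)
    }
    k1 <- keyify(tr1); k2 <- keyify(tr2)
    keys <- sort(unique(c(k1, k2)))
    if (!length(keys)) next
    rd1 <- vapply(keys, function(kk)
      relative_density(tr1[k1 == kk, , drop = FALSE], model, ft), numeric(1))
    rd2 <- vapply(keys, function(kk)
      relative_density(tr2[k2 == kk, , drop = FALSE], model, ft), numeric(1))
    parts <- strsplit(keys, "|", fixed = TRUE)
    rec <- data.frame(
      plot_id = t2row$plot_id,
      species_code = as.integer(vapply(parts, `[`, "", 1)),
      rd_t1 = unname(rd1), rd_t2 = unname(rd2),
      delta_t = t2row$delta_t,
      fsi = unname(fsi(rd1, rd2, t2row$delta_t)),
      stratum_id = t2row$stratum_id,
      ecoregion_division = t2row$ecoregion_division,
      ecoregion_subsection = t2row$ecoregion_subsection,
      forest_type = ft,
      fire = t2row$fire, insect = t2row$insect, disease = t2row$disease,
      panel = t2row$census_year,
      stringsAsFactors = FALSE
    )
    if (by_size_class)
      rec$size_class <- as.integer(vapply(parts, `[`, "", 2))
    out[[k]] <- rec
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no eligible census pairs", call. = FALSE)
  rownames(res) <- NULL
  res
}
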