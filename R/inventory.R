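#' Column dialect for inventory CSV files
#'
#' Describes how plot- and tree-level CSV files map onto the columns this
#' package needs, in the style of the USDA FIA datamart tables (a plot/cond
#' table keyed by `CN` with a `PREV_PLT_CN` linkage column, and a tree table
#' keyed by `PLT_CN`). The default dialect is the package's canonical one:
#' diameters in centimetres and per-tree expansion factors in stems per
#' hectare. Raw FIA extracts use inches and trees per acre; set `dia_unit` and
#' `density_unit` accordingly and values are normalized on read (1 acre^-1 =
#' 2.4710538 ha^-1, 1 in = 2.54 cm).
#'
#' @param dia_unit unit of the tree diameter column, `"cm"` or `"in"`.
#' @param density_unit unit of the expansion-factor column, `"per_ha"` or
#'   `"per_acre"`.
#' @param columns named list overriding any of the default column names (see
#'   `fia_dialect()$columns` for the full set).
#' @return an object of class `"fia_dialect"`.
#' @export
fia_dialect <- function(dia_unit = c("cm", "in"),
                        density_unit = c("per_ha", "per_acre"),
                        columns = list()) {
  dia_unit <- match.arg(dia_unit)
  density_unit <- match.arg(density_unit)
  def <- list(
    plot_id = "CN", prev_plot_id = "PREV_PLT_CN", year = "MEASYEAR",
    forest_type = "FORTYPCD", site_class = "SITECLCD",
    division = "ECODIV", subsection = "ECOSUBCD", stratum = "STRATUM_CN",
    disturb = c("DSTRBCD1", "DSTRBCD2", "DSTRBCD3"),
    treat = c("TRTCD1", "TRTCD2", "TRTCD3"),
    treat_year = c("TRTYR1", "TRTYR2", "TRTYR3"),
    tree_id = "CN", tree_plot_id = "PLT_CN", species = "SPCD",
    dia = "DIA", status = "STATUSCD", expansion = "TPA_UNADJ"
  )
  stopifnot(all(names(columns) %in% names(def)))
  def[names(columns)] <- columns
  structure(list(dia_unit = dia_unit, density_unit = density_unit,
                 columns = def),
            class = "fia_dialect")
}

ACRE_TO_HA <- 2.4710538

#' Basal area of a stem from its diameter
#'
#' @param dbh diameter at breast height, cm.
#' @return stem basal area in m^2 (`pi * dbh^2 / 40000`).
#' @export
basal_area <- function(dbh) pi * dbh^2 / 40000

.require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing required column(s) in ", file, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
}

# FIA-style condition disturbance code -> agent class
.disturb_class <- function(code) {
  out <- rep(NA_character_, length(code))
  out[!is.na(code) & code >= 10 & code < 20] <- "insect"
  out[!is.na(code) & code >= 20 & code < 30] <- "disease"
  out[!is.na(code) & code >= 30 & code < 40] <- "fire"
  out[!is.na(code) & code > 0 & is.na(out)] <- "other"
  out
}

#' Read a remeasured forest inventory from plot and tree CSV files
#'
#' Parses an FIA-datamart-like pair of CSV files into a normalized inventory:
#' one row per plot census (with interval disturbance/treatment flags and the
#' linkage to the previous census of the same plot) and one row per tree
#' record. Censuses are paired strictly through the previous-plot key; a
#' census whose key matches no record is retained but flagged unpaired and is
#' excluded from change analysis.
#'
#' @param plot_csv path to the plot-level CSV.
#' @param tree_csv path to the tree-level CSV.
#' @param dialect a [fia_dialect()] describing columns and units.
#' @return an object of class `"fsi_inventory"`: a list with data frames
#'   `plots` (one row per census; columns `plot_id`, `prev_plot_id`,
#'   `census_year`, `forest_type`, `site_class`, `ecoregion_division`,
#'   `ecoregion_subsection`, `stratum_id`, `fire`, `insect`, `disease`,
#'   `other_disturbance`, `treated`, `treatment_year`, `paired`, `prev_year`,
#'   `delta_t`) and `trees` (`plot_id`, `tree_id`, `species_code`, `dbh` (cm),
#'   `status`, `density_factor` (stems/ha), `basal_area` (m^2)).
#' @export
read_inventory <- function(plot_csv, tree_csv, dialect = fia_dialect()) {
  cl <- dialect$columns
  praw <- utils::read.csv(plot_csv, stringsAsFactors = FALSE)
  traw <- utils::read.csv(tree_csv, stringsAsFactors = FALSE)
  .require_cols(praw, unlist(cl[c("plot_id", "prev_plot_id", "year",
                                  "forest_type", "site_class", "division",
                                  "subsection", "stratum", "disturb",
                                  "treat")]), plot_csv)
  .require_cols(traw, unlist(cl[c("tree_id", "tree_plot_id", "species",
                                  "dia", "status", "expansion")]), tree_csv)

  dist <- sapply(cl$disturb, function(col) .disturb_class(praw[[col]]))
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = nrow(praw))
  has <- function(what) as.integer(apply(dist == what, 1, any, na.rm = TRUE))
  trt <- sapply(cl$treat, function(col) {
    v <- praw[[col]]
    !is.na(v) & v > 0
  })
  if (is.null(dim(trt))) trt <- matrix(trt, nrow = nrow(praw))
  treated <- as.integer(apply(trt, 1, any))
  trt_yr <- rep(NA_real_, nrow(praw))
  if (all(cl$treat_year %in% names(praw))) {
    yrs <- sapply(cl$treat_year, function(col) as.numeric(praw[[col]]))
    if (is.null(dim(yrs))) yrs <- matrix(yrs, nrow = nrow(praw))
    yrs[!trt] <- NA
    trt_yr <- suppressWarnings(apply(yrs, 1, min, na.rm = TRUE))
    trt_yr[!is.finite(trt_yr)] <- NA_real_
  }
  # treatment with no recorded year is taken to fall in the interval
  trt_yr[treated == 1 & is.na(trt_yr)] <-
    praw[[cl$year]][treated == 1 & is.na(trt_yr)]

  plots <- data.frame(
    plot_id = as.character(praw[[cl$plot_id]]),
    prev_plot_id = as.character(praw[[cl$prev_plot_id]]),
    census_year = as.numeric(praw[[cl$year]]),
    forest_type = as.character(praw[[cl$forest_type]]),
    site_class = as.integer(praw[[cl$site_class]]),
    ecoregion_division = as.character(praw[[cl$division]]),
    ecoregion_subsection = as.character(praw[[cl$subsection]]),
    stratum_id = as.character(praw[[cl$stratum]]),
    fire = has("fire"), insect = has("insect"), disease = has("disease"),
    other_disturbance = has("other"),
    treated = treated, treatment_year = trt_yr,
    stringsAsFactors = FALSE
  )
  plots$prev_plot_id[plots$prev_plot_id %in% c("", "NA")] <- NA_character_
  plots$paired <- !is.na(plots$prev_plot_id) &
    plots$prev_plot_id %in% plots$plot_id
  idx <- match(plots$prev_plot_id, plots$plot_id)
  plots$prev_year <- ifelse(plots$paired, plots$census_year[idx], NA_real_)
  plots$delta_t <- plots$census_year - plots$prev_year
  bad <- which(plots$paired & plots$delta_t <= 0)
  if (length(bad))
    stop("non-positive remeasurement interval for plot census(es): ",
         paste(plots$plot_id[bad], collapse = ", "), call. = FALSE)

  dbh <- as.numeric(traw[[cl$dia]])
  if (dialect$dia_unit == "in") dbh <- dbh * 2.54
  dens <- as.numeric(traw[[cl$expansion]])
  if (dialect$density_unit == "per_acre") dens <- dens * ACRE_TO_HA
  status_raw <- traw[[cl$status]]
  status <- if (is.numeric(status_raw)) {
    ifelse(status_raw == 1, "live", "dead")
  } else as.character(status_raw)
  trees <- data.frame(
    plot_id = as.character(traw[[cl$tree_plot_id]]),
    tree_id = as.character(traw[[cl$tree_id]]),
    species_code = as.integer(traw[[cl$species]]),
    dbh = dbh, status = status, density_factor = dens,
    basal_area = basal_area(dbh),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(trees$density_factor) | trees$density_factor < 0))
    stop("tree expansion factors must be finite and non-negative",
         call. = FALSE)
  structure(list(plots = plots, trees = trees), class = "fsi_inventory")
}

#' Write an inventory in the canonical CSV dialect
#'
#' Writes the plot and tree tables of an [read_inventory()] inventory as CSV
#' files in the canonical dialect (cm, stems/ha), such that reading them back
#' reproduces the inventory.
#'
#' @param inventory an `"fsi_inventory"` object.
#' @param plot_csv,tree_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_inventory <- function(inventory, plot_csv, tree_csv) {
  stopifnot(inherits(inventory, "fsi_inventory"))
  p <- inventory$plots
  # re-emit one representative condition code per agent class
  dm <- cbind(ifelse(p$insect == 1, 10, 0), ifelse(p$disease == 1, 20, 0),
              ifelse(p$fire == 1, 30, 0))
  # put 'other' (code 90) into the first free slot
  for (i in which(p$other_disturbance == 1)) {
    free <- which(dm[i, ] == 0)
    if (length(free)) dm[i, free[1]] <- 90
  }
  pout <- data.frame(
    CN = p$plot_id, PREV_PLT_CN = ifelse(is.na(p$prev_plot_id), "",
                                         p$prev_plot_id),
    MEASYEAR = p$census_year, FORTYPCD = p$forest_type,
    SITECLCD = p$site_class, ECODIV = p$ecoregion_division,
    ECOSUBCD = p$ecoregion_subsection, STRATUM_CN = p$stratum_id,
    DSTRBCD1 = dm[, 1], DSTRBCD2 = dm[, 2], DSTRBCD3 = dm[, 3],
    TRTCD1 = ifelse(p$treated == 1, 10, 0), TRTCD2 = 0, TRTCD3 = 0,
    TRTYR1 = ifelse(p$treated == 1, p$treatment_year, NA),
    TRTYR2 = NA, TRTYR3 = NA,
    stringsAsFactors = FALSE
  )
  tr <- inventory$trees
  tout <- data.frame(
    CN = tr$tree_id, PLT_CN = tr$plot_id, SPCD = tr$species_code,
    DIA = tr$dbh, STATUSCD = ifelse(tr$status == "live", 1L, 2L),
    TPA_UNADJ = tr$density_factor,
    stringsAsFactors = FALSE
  )
  utils::write.csv(pout, plot_csv, row.names = FALSE, na = "")
  utils::write.csv(tout, tree_csv, row.names = FALSE, na = "")
  invisible(c(plot_csv, tree_csv))
}

#' @export
print.fsi_inventory <- function(x, ...) {
  cat("Forest inventory:", nrow(x$plots), "plot censuses (",
      sum(x$plots$paired), "paired ),", nrow(x$trees), "tree records\n")
  invisible(x)
}

#' Pearson's moment coefficient of skewness
#'
#' The population-moment estimator g1 = m3 / m2^(3/2) with n-denominator
#' central moments, computed on an unweighted sample.
#'
#' @param x numeric sample (at least 3 values for a defined result).
#' @return g1, or `NA` for fewer than 3 values or a degenerate sample.
#' @export
dbh_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

.stand_summary_one <- function(dbh, density_factor, status) {
  keep <- status == "live" & dbh >= 2.54
  dbh <- dbh[keep]; df <- density_factor[keep]
  tph <- sum(df)
  ba_ha <- sum(df * basal_area(dbh))
  list(tph = tph, ba_per_ha = ba_ha,
       mean_tree_ba = if (tph > 0) ba_ha / tph else NA_real_,
       diameter_skewness = dbh_skewness(dbh),
       n_live = length(dbh))
}

#' Stand-level summaries of every plot census
#'
#' Computes, for each census, total live-tree density (TPH, stems/ha), basal
#' area per hectare, mean tree basal area (the size index: basal area per
#' hectare divided by TPH) and the unweighted skewness of the measured DBH
#' list. Only live stems with DBH >= 2.54 cm contribute.
#'
#' @param inventory an `"fsi_inventory"`.
#' @return data frame with one row per census: the `plots` columns plus
#'   `tph`, `ba_per_ha`, `mean_tree_ba`, `diameter_skewness`, `n_live`.
#'   `mean_tree_ba` and `diameter_skewness` are `NA` for empty stands.
#' @export
summarize_stands <- function(inventory) {
  stopifnot(inherits(inventory, "fsi_inventory"))
  p <- inventory$plots
  tr <- inventory$trees
  idx <- split(seq_len(nrow(tr)), factor(tr$plot_id, levels = p$plot_id))
  sm <- lapply(idx, function(i)
    .stand_summary_one(tr$dbh[i], tr$density_factor[i], tr$status[i]))
  cbind(p, do.call(rbind, lapply(sm, function(s)
    data.frame(tph = s$tph, ba_per_ha = s$ba_per_ha,
               mean_tree_ba = s$mean_tree_ba,
               diameter_skewness = s$diameter_skewness,
               n_live = s$n_live))), row.names = NULL)
}

#' Select stands eligible for frontier fitting
#'
#' Keeps the most recent census of every plot when it shows no disturbance or
#' silvicultural treatment within the remeasurement interval or the preceding
#' 5 years, and its diameter distribution is approximately normal (skewness
#' within `skew_range`). Stands with fewer than 3 live stems cannot be
#' screened for normality and are excluded. Binary disturbance flags carry no
#' event year, so any disturbance recorded at the previous census also
#' excludes the plot (conservative reading of the 5-year look-back).
#'
#' @param inventory an `"fsi_inventory"`.
#' @param skew_range closed interval of admissible DBH skewness.
#' @return list with `kept` (stand-summary rows of eligible censuses) and
#'   `excluded` (data frame of `plot_id`, `reason` in
#'   `c("disturbed", "treated", "skewness", "too_few_stems")`).
#' @export
filter_frontier_training <- function(inventory, skew_range = c(-1, 1)) {
  st <- summarize_stands(inventory)
  terminal <- !(st$plot_id %in% st$prev_plot_id[!is.na(st$prev_plot_id)])
  st <- st[terminal, , drop = FALSE]
  prev <- summarize_stands(inventory)
  prev <- prev[match(st$prev_plot_id, prev$plot_id), , drop = FALSE]

  disturbed <- (st$fire | st$insect | st$disease | st$other_disturbance) == 1
  prev_dist <- st$paired &
    (prev$fire | prev$insect | prev$disease | prev$other_disturbance) == 1
  disturbed <- disturbed | (prev_dist %in% TRUE)
  treated <- st$treated == 1
  prev_trt <- st$paired & prev$treated == 1 &
    !is.na(prev$treatment_year) & prev$treatment_year >= st$prev_year - 5
  treated <- treated | (prev_trt %in% TRUE)
  few <- st$n_live < 3
  skewed <- !few & (is.na(st$diameter_skewness) |
                      st$diameter_skewness < skew_range[1] |
                      st$diameter_skewness > skew_range[2])

  reason <- rep(NA_character_, nrow(st))
  reason[skewed] <- "skewness"
  reason[few] <- "too_few_stems"
  reason[treated] <- "treated"
  reason[disturbed] <- "disturbed"
  keep <- is.na(reason)
  list(kept = st[keep, , drop = FALSE],
       excluded = data.frame(plot_id = st$plot_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Select census pairs eligible for change analysis
#'
#' Keeps paired censuses, excluding pairs with silvicultural treatment during
#' the remeasurement interval or within 5 years before the initial
#' measurement. Disturbance never excludes a pair here: it is a modeled
#' covariate of change, not a data defect.
#'
#' @param inventory an `"fsi_inventory"`.
#' @return list with `kept` (rows of `plots` for the second census of each
#'   eligible pair) and `excluded` (`plot_id`, `reason`).
#' @export
filter_change_analysis <- function(inventory) {
  p <- inventory$plots
  t2 <- p[p$paired, , drop = FALSE]
  t1 <- p[match(t2$prev_plot_id, p$plot_id), , drop = FALSE]
  trt_interval <- t2$treated == 1
  trt_before <- t1$treated == 1 & !is.na(t1$treatment_year) &
    t1$treatment_year >= t2$prev_year - 5
  drop <- trt_interval | trt_before
  list(kept = t2[!drop, , drop = FALSE],
       excluded = data.frame(plot_id = t2$plot_id[drop],
                             reason = rep("treated", sum(drop)),
                             stringsAsFactors = FALSE))
}
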