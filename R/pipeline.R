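#' Run the full stability-index pipeline
#'
#' Config-driven orchestration of every stage: obtain an inventory (either
#' generated from a synthetic-landscape config or read from CSV files),
#' apply the eligibility filters, fit the size-density frontier on the
#' training stands, compute per-plot population change records, estimate
#' population-level change with post-stratified annual-panel estimators, and
#' attribute change to disturbance with the severity x probability model.
#' Every stochastic stage consumes a sub-seed derived from the run seed, so
#' identical config and seed reproduce identical outputs.
#'
#' @param config either a path to a YAML file or a list with elements:
#'   `seed` (integer, mandatory); one of `synth` (arguments for
#'   [landscape_config()], seed filled from the run seed) or `input`
#'   (`plot_csv`, `tree_csv`, optional dialect arguments); optional
#'   `frontier` (mcmc settings passed to [fit_frontier()]), `estimation`
#'   (`by` groupers), `disturbance` (mcmc settings), `by_size_class`.
#' @param out_dir optional directory; when given, writes `records.csv`,
#'   `estimates.csv`, `effects.csv` and `manifest.json` there.
#' @return invisibly, a list with `inventory`, `training`, `frontier`,
#'   `records`, `estimates`, `effects` and `manifest` (stage record counts,
#'   seeds, file hashes).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "fsindex",
                   version = as.character(utils::packageVersion("fsindex")),
                   seed = seed, stages = list())

  truth <- NULL
  scheme <- NULL
  if (!is.null(config$synth)) {
    args <- config$synth
    args$seed <- (seed * 17L) %% 2147483647L
    if (!is.null(args$psi)) args$psi <- matrix(unlist(args$psi), ncol = 3)
    if (!is.null(args$beta)) args$beta <- matrix(unlist(args$beta), ncol = 3)
    land <- generate_landscape(do.call(landscape_config, args))
    inv <- land$inventory
    scheme <- stratification_scheme(land$scheme$stratum_id, land$scheme$W)
    truth <- land$truth
  } else if (!is.null(config$input)) {
    dialect <- do.call(fia_dialect, config$input$dialect %||% list())
    inv <- read_inventory(config$input$plot_csv, config$input$tree_csv,
                          dialect)
    if (!is.null(config$input$strata_csv)) {
      sdf <- utils::read.csv(config$input$strata_csv,
                             stringsAsFactors = FALSE)
      scheme <- stratification_scheme(sdf$stratum_id, sdf$W)
    } else {
      tab <- table(inv$plots$stratum_id)
      scheme <- stratification_scheme(names(tab),
                                      as.numeric(tab) / sum(tab))
    }
  } else stop("config needs either 'synth' or 'input'", call. = FALSE)
  manifest$stages$inventory <- list(plot_censuses = nrow(inv$plots),
                                    tree_records = nrow(inv$trees))

  ftrain <- filter_frontier_training(inv)
  manifest$stages$frontier_filter <- list(
    plots_in = nrow(ftrain$kept) + nrow(ftrain$excluded),
    plots_kept = nrow(ftrain$kept),
    excluded_by_reason = as.list(table(ftrain$excluded$reason)))

  fargs <- config$frontier %||% list()
  fargs$stands <- ftrain$kept
  fargs$seed <- (seed * 23L) %% 2147483647L
  frontier <- do.call(fit_frontier, fargs)

  pairs <- filter_change_analysis(inv)
  manifest$stages$change_filter <- list(
    plots_in = nrow(pairs$kept) + nrow(pairs$excluded),
    plots_kept = nrow(pairs$kept),
    excluded_by_reason = as.list(table(pairs$excluded$reason)))

  records <- population_change(inv, frontier,
                               by_size_class = isTRUE(config$by_size_class))
  manifest$stages$records <- list(n = nrow(records))

  by <- config$estimation$by %||% character(0)
  estimates <- grouped_estimates(records, pairs$kept, scheme, by = by)
  manifest$stages$estimates <- list(n = nrow(estimates))

  sp_records <- if (isTRUE(config$by_size_class))
    population_change(inv, frontier) else records
  obs <- disturbance_observations(sp_records)
  dargs <- config$disturbance %||% list()
  sev <- do.call(fit_severity, c(list(obs = obs,
                                      seed = (seed * 29L) %% 2147483647L),
                                 dargs))
  prob <- do.call(fit_probability,
                  c(list(obs = obs, seed = (seed * 31L) %% 2147483647L),
                    dargs))
  rd_bar <- tapply(obs$rd_t1, obs$species_code, mean)
  effects <- standardized_effect(sev, prob, rd_bar)
  manifest$stages$disturbance <- list(species = length(sev$species),
                                      draws = sev$n_draws)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, c("records.csv", "estimates.csv",
                                  "effects.csv"))
    utils::write.csv(records, paths[1], row.names = FALSE)
    utils::write.csv(estimates, paths[2], row.names = FALSE)
    utils::write.csv(effects$summary, paths[3], row.names = FALSE)
    manifest$files <- as.list(tools::md5sum(paths))
    names(manifest$files) <- basename(paths)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(inventory = inv, training = ftrain, frontier = frontier,
                 records = records, estimates = estimates,
                 severity = sev, probability = prob, effects = effects,
                 truth = truth, scheme = scheme, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
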