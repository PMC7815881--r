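test_that("reading normalizes units and links censuses through the previous-plot key", {
  pd <- tempfile(fileext = ".csv"); td <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    CN = c("A1", "A2", "B1"), PREV_PLT_CN = c("", "A1", "ZZZ"),
    MEASYEAR = c(2005, 2015, 2012), FORTYPCD = "FT01", SITECLCD = 3,
    ECODIV = "DIV1", ECOSUBCD = "SUBA", STRATUM_CN = "S1",
    DSTRBCD1 = c(0, 31, 0), DSTRBCD2 = 0, DSTRBCD3 = 0,
    TRTCD1 = 0, TRTCD2 = 0, TRTCD3 = 0), pd, row.names = FALSE)
  write.csv(data.frame(
    CN = c("t1", "t2"), PLT_CN = c("A2", "A2"), SPCD = 101,
    DIA = c(10, 50), STATUSCD = c(1, 2), TPA_UNADJ = c(74.97, 10)),
    td, row.names = FALSE)
  inv <- read_inventory(pd, td)

  expect_true(inv$plots$paired[inv$plots$plot_id == "A2"])
  expect_equal(inv$plots$delta_t[inv$plots$plot_id == "A2"], 10)
  # unmatched previous-plot key: retained but unpaired
  expect_false(inv$plots$paired[inv$plots$plot_id == "B1"])
  # fire code 31 maps to the fire flag
  expect_equal(inv$plots$fire[inv$plots$plot_id == "A2"], 1L)

  st <- summarize_stands(inv)
  a2 <- st[st$plot_id == "A2", ]
  # dead stem excluded from all totals
  expect_equal(a2$tph, 74.97)
  expect_equal(a2$ba_per_ha, 74.97 * pi * 100 / 40000)
  expect_equal(a2$mean_tree_ba, pi * 100 / 40000, tolerance = 1e-12)
})

test_that("FIA-unit dialect converts inches and per-acre expansion factors", {
  pd <- tempfile(fileext = ".csv"); td <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    CN = "A", PREV_PLT_CN = "", MEASYEAR = 2012, FORTYPCD = "F",
    SITECLCD = 1, ECODIV = "D", ECOSUBCD = "S", STRATUM_CN = "S1",
    DSTRBCD1 = 0, DSTRBCD2 = 0, DSTRBCD3 = 0,
    TRTCD1 = 0, TRTCD2 = 0, TRTCD3 = 0), pd, row.names = FALSE)
  write.csv(data.frame(CN = "t", PLT_CN = "A", SPCD = 101, DIA = 10 / 2.54,
                       STATUSCD = 1, TPA_UNADJ = 30), td, row.names = FALSE)
  inv <- read_inventory(pd, td,
                        fia_dialect(dia_unit = "in",
                                    density_unit = "per_acre"))
  expect_equal(inv$trees$dbh, 10)
  expect_equal(inv$trees$density_factor, 30 * 2.4710538)
})

test_that("schema and pairing defects raise named errors", {
  pd <- tempfile(fileext = ".csv"); td <- tempfile(fileext = ".csv")
  write.csv(data.frame(CN = "A", PREV_PLT_CN = "", MEASYEAR = 2012),
            pd, row.names = FALSE)
  write.csv(data.frame(CN = "t", PLT_CN = "A", SPCD = 1, DIA = 10,
                       STATUSCD = 1, TPA_UNADJ = 1), td, row.names = FALSE)
  expect_error(read_inventory(pd, td), "FORTYPCD")

  write.csv(data.frame(
    CN = c("A1", "A2"), PREV_PLT_CN = c("", "A1"),
    MEASYEAR = c(2015, 2010), FORTYPCD = "F", SITECLCD = 1, ECODIV = "D",
    ECOSUBCD = "S", STRATUM_CN = "S1", DSTRBCD1 = 0, DSTRBCD2 = 0,
    DSTRBCD3 = 0, TRTCD1 = 0, TRTCD2 = 0, TRTCD3 = 0),
    pd, row.names = FALSE)
  expect_error(read_inventory(pd, td), "non-positive")
})

test_that("stand summaries follow the unweighted moment skewness", {
  expect_equal(dbh_skewness(c(1, 2, 3)), 0)
  # hand computation: m3 / m2^1.5 with n-denominators
  x <- c(1, 1, 1, 10)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  expect_equal(dbh_skewness(x), m3 / m2^1.5)
  expect_equal(dbh_skewness(x), 1.1547005, tolerance = 1e-6)
  expect_true(is.na(dbh_skewness(c(1, 2))))
  expect_true(is.na(dbh_skewness(rep(5, 8))))

  tr <- tree_rows("P", dbh = c(11.28379, 19.54410), density_factor = 100)
  tr$basal_area <- c(0.01, 0.03)  # exact sizes for the arithmetic check
  inv <- new_inventory(plot_row("P", year = 2012), tr)
  inv$trees <- tr
  st <- summarize_stands(inv)
  expect_equal(st$tph, 200)
  expect_equal(st$ba_per_ha, 100 * 0.01 + 100 * 0.03, tolerance = 1e-6)
  expect_equal(st$mean_tree_ba, 0.02, tolerance = 1e-6)
})

test_that("summaries are additive over merged tree lists", {
  a <- random_stand(12); b <- random_stand(7)
  b$plot_id <- "X"
  inv_a <- new_inventory(plot_row("X", year = 2012), a)
  inv_b <- new_inventory(plot_row("X", year = 2012), b)
  inv_ab <- new_inventory(plot_row("X", year = 2012), rbind(a, b))
  expect_equal(summarize_stands(inv_ab)$tph,
               summarize_stands(inv_a)$tph + summarize_stands(inv_b)$tph)
})

test_that("frontier training filter excludes disturbed, treated, skewed and tiny stands", {
  plots <- rbind(
    plot_row("D1", year = 2005), plot_row("D2", "D1", 2015, fire = 1L),
    plot_row("T1", year = 2005), plot_row("T2", "T1", 2015, treated = 1L,
                                          trt_yr = 2010),
    plot_row("S", year = 2015),
    plot_row("N", year = 2015),
    plot_row("F", year = 2015),
    plot_row("PT1", year = 2005, treated = 1L, trt_yr = 1998),
    plot_row("PT2", "PT1", 2015)
  )
  trees <- rbind(
    tree_rows("D2", c(10, 12, 14), 50), tree_rows("T2", c(10, 12, 14), 50),
    tree_rows("S", c(10, 10, 10, 100), 50),  # skewness ~ 1.15 > 1
    tree_rows("N", c(10, 12, 14), 50),
    tree_rows("F", c(10, 12), 50),           # two stems: unscreenable
    tree_rows("PT2", c(10, 12, 14), 50)
  )
  out <- filter_frontier_training(new_inventory(plots, trees))
  reasons <- setNames(out$excluded$reason, out$excluded$plot_id)
  expect_equal(reasons[["D2"]], "disturbed")
  expect_equal(reasons[["T2"]], "treated")
  expect_equal(reasons[["S"]], "skewness")
  expect_equal(reasons[["F"]], "too_few_stems")
  expect_true("N" %in% out$kept$plot_id)
  # treatment 7 years before the interval start is outside the look-back
  expect_true("PT2" %in% out$kept$plot_id)
  # bookkeeping: every terminal census is either kept or excluded
  expect_equal(nrow(out$kept) + nrow(out$excluded), 6)
})

test_that("change-analysis filter drops recent treatment but keeps disturbance", {
  plots <- rbind(
    plot_row("A1", year = 2005, treated = 1L, trt_yr = 2002),  # 3 yr before
    plot_row("A2", "A1", 2015),
    plot_row("B1", year = 2005), plot_row("B2", "B1", 2015, fire = 1L),
    plot_row("C1", year = 2005, treated = 1L, trt_yr = 1995),  # 10 yr before
    plot_row("C2", "C1", 2015),
    plot_row("E1", year = 2005), plot_row("E2", "E1", 2015, treated = 1L,
                                          trt_yr = 2010)
  )
  trees <- tree_rows("B2", c(10, 12, 14), 50)
  out <- filter_change_analysis(new_inventory(plots, trees))
  expect_setequal(out$kept$plot_id, c("B2", "C2"))
  expect_setequal(out$excluded$plot_id, c("A2", "E2"))
  expect_true(all(out$excluded$reason == "treated"))
})

test_that("filters are idempotent", {
  cfg <- landscape_config(n_plots = 40, seed = 11,
                          psi = matrix(0.05, 3, 3))
  inv <- generate_landscape(cfg)$inventory
  once <- filter_change_analysis(inv)
  keep_ids <- c(once$kept$plot_id, once$kept$prev_plot_id)
  inv2 <- inv
  inv2$plots <- inv$plots[inv$plots$plot_id %in% keep_ids, ]
  inv2$trees <- inv$trees[inv$trees$plot_id %in% keep_ids, ]
  twice <- filter_change_analysis(inv2)
  expect_setequal(twice$kept$plot_id, once$kept$plot_id)
  expect_equal(nrow(twice$excluded), 0)

  ft_once <- filter_frontier_training(inv)
  inv3 <- inv
  keep3 <- c(ft_once$kept$plot_id, ft_once$kept$prev_plot_id)
  inv3$plots <- inv$plots[inv$plots$plot_id %in% keep3, ]
  inv3$trees <- inv$trees[inv$trees$plot_id %in% keep3, ]
  ft_twice <- filter_frontier_training(inv3)
  expect_setequal(ft_twice$kept$plot_id, ft_once$kept$plot_id)
  expect_equal(nrow(ft_twice$excluded), 0)
})

test_that("write/read round-trips the canonical dialect", {
  cfg <- landscape_config(n_plots = 25, seed = 5,
                          psi = matrix(c(0.1, 0.02, 0.01), 3, 3))
  inv <- generate_landscape(cfg)$inventory
  pd <- tempfile(fileext = ".csv"); td <- tempfile(fileext = ".csv")
  write_inventory(inv, pd, td)
  back <- read_inventory(pd, td)
  i <- order(back$plots$plot_id); j <- order(inv$plots$plot_id)
  for (col in c("plot_id", "census_year", "forest_type", "fire", "insect",
                "disease", "treated", "paired", "delta_t", "stratum_id",
                "ecoregion_subsection"))
    expect_equal(back$plots[[col]][i], inv$plots[[col]][j], info = col)
  k <- order(back$trees$tree_id); l <- order(inv$trees$tree_id)
  for (col in c("species_code", "dbh", "density_factor", "status"))
    expect_equal(back$trees[[col]][k], inv$trees[[col]][l], info = col,
                 tolerance = 1e-9)
})
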