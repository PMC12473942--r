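test_that("germination CSV loads, validates, and reports bad rows by line", {
  path <- write_germ_csv("lotA,RT,0,1,20,18")
  rec <- load_germination_table(path)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_germ, 18)
  expect_equal(rec$lot_id, "lotA")

  bad <- write_germ_csv(c("lotA,RT,0,1,20,18", "lotA,RT,7,2,20,25"))
  expect_error(load_germination_table(bad), "row 3.*n_germ")

  dir <- withr::local_tempdir()
  nocol <- file.path(dir, "nocol.csv")
  writeLines(c("lot_id,regime_id,time_d,n_sown,n_germ", "a,r,0,20,10"), nocol)
  expect_error(load_germination_table(nocol), "schema error.*replicate")
})

test_that("a 5-replicate x 4-time design loads as 20 records in 4 groups", {
  lines <- as.vector(outer(0:3 * 30, 1:5, function(t, r) {
    sprintf("lotA,dry,%d,%d,20,%d", t, r, 20 - t %/% 30)
  }))
  rec <- load_germination_table(write_germ_csv(lines))
  expect_equal(nrow(rec), 20L)
  expect_equal(length(unique(rec$time_d)), 4L)
  expect_equal(nrow(summarize_germination(rec)), 4L)
})

test_that("write/load round-trips a germination table exactly", {
  sim <- simulate_lot(lot_simulation_config(6, 200, c(0, 60, 120), rng_seed = 5))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.csv")
  write_germination_table(sim$records, path)
  back <- load_germination_table(path)
  expect_identical(back, sim$records)
})

test_that("summarize_germination matches hand arithmetic", {
  rec <- data.frame(lot_id = "a", regime_id = "r", time_d = 0,
                    replicate = 1:5, n_sown = 20, n_germ = c(17, 20, 20, 20, 20))
  s <- summarize_germination(rec)
  expect_equal(s$mean_pct, 97)
  # pcts {85,100,100,100,100}: var = 45, SE = sqrt(45)/sqrt(5) = 3
  expect_equal(s$se_pct, 3)
  expect_equal(s$n_reps, 5L)

  const <- rec; const$n_germ <- 20
  expect_equal(summarize_germination(const)$mean_pct, 100)
  expect_equal(summarize_germination(const)$se_pct, 0)

  empty <- rec[0, ]
  expect_equal(nrow(summarize_germination(empty)), 0L)
})

test_that("identical replicate groups across k reps give SE exactly 0", {
  for (k in c(2, 5, 8)) {
    rec <- data.frame(lot_id = "a", regime_id = "r", time_d = 0,
                      replicate = 1:k, n_sown = 20, n_germ = 13)
    expect_identical(summarize_germination(rec)$se_pct, 0)
  }
})

test_that("compare_groups separates a drastic viability drop and keeps equals together", {
  # fresh vs dried at the green-capsule stage: ~98 +/- 1.7 vs 7 +/- 2.5
  fresh <- c(100, 100, 100, 100, 91.65)
  dry <- c(0, 5, 5, 10, 15)
  cg <- compare_groups(c(fresh, dry), rep(c("fresh", "dry"), each = 5),
                       control = "fresh")
  expect_lt(cg$anova["p"], 0.05)
  expect_true(cg$groups$significant_vs_control[cg$groups$group == "dry"])
  expect_false(cg$groups$letter[cg$groups$group == "dry"] ==
                 cg$groups$letter[cg$groups$group == "fresh"])

  # identical constant groups: zero-variance fallback, not significant
  expect_warning(
    cg0 <- compare_groups(rep(50, 10), rep(c("a", "b"), each = 5), control = "a"),
    "zero within-group variance"
  )
  expect_false(any(cg0$groups$significant_vs_control))
})

test_that("compare_groups is symmetric in group labels", {
  set.seed(42)
  x <- 100 * rbinom(10, 20, 0.8) / 20
  g1 <- rep(c("a", "b"), each = 5)
  g2 <- rep(c("b", "a"), each = 5)
  c1 <- compare_groups(x, g1, control = "a")
  c2 <- compare_groups(x, g2, control = "b")
  expect_equal(unname(c1$anova["p"]), unname(c2$anova["p"]))
  expect_equal(c1$groups$significant_vs_control[c1$groups$group == "b"],
               c2$groups$significant_vs_control[c2$groups$group == "a"])
})

test_that("SNK letters order clearly separated means and share letters for close ones", {
  set.seed(7)
  x <- c(rnorm(5, 98, 2), rnorm(5, 96, 2), rnorm(5, 40, 2))
  g <- rep(c("hi1", "hi2", "lo"), each = 5)
  cg <- compare_groups(x, g)
  lt <- setNames(cg$groups$letter, cg$groups$group)
  expect_equal(lt[["hi1"]], lt[["hi2"]])
  expect_false(lt[["lo"]] == lt[["hi1"]])
})

test_that("assumption diagnostics warn but never gate the ANOVA", {
  set.seed(1)
  # wildly heteroscedastic groups to trip Levene
  x <- c(rnorm(10, 50, 0.01), rnorm(10, 60, 25))
  g <- rep(c("a", "b"), each = 10)
  w <- testthat::capture_warnings(cg <- compare_groups(x, g, diagnostics = TRUE))
  expect_true(any(grepl("questionable", w)))
  expect_s3_class(cg, "group_comparison")
  expect_false(is.na(cg$anova["p"]))
})

test_that("bundled maturity table matches the published layout", {
  tab <- maturity_table()
  expect_equal(nrow(tab), 40L)
  expect_setequal(unique(tab$water_status), c("fresh", "dry"))
  yellow <- tab[tab$stage == "yellow", ]
  expect_true(all(yellow$mean_pct == 100 & yellow$se_pct == 0))
})

test_that("seed-lot loader validates genus and parses dates", {
  lots <- load_seed_lots()
  expect_equal(nrow(lots), 19L)
  expect_setequal(unique(lots$genus), c("Salix", "Populus"))
  expect_s3_class(lots$collection_date, "Date")
  expect_true(sum(is.na(lots$collection_date)) == 1L) # one incomplete date
  expect_true(all(lots$elevation_m >= 0))
})

test_that("regime loader enforces RH and MC ranges", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "regimes.csv")
  writeLines(c("regime_id,temperature_C,rh_pct,label",
               "dry_room,15,15,dry room", "LN,-196,,liquid nitrogen"), path)
  reg <- load_storage_regimes(path)
  expect_equal(nrow(reg), 2L)
  expect_true(is.na(reg$rh_pct[2]))
  writeLines(c("regime_id,temperature_C,rh_pct,label", "x,20,150,bad"), path)
  expect_error(load_storage_regimes(path), "rh_pct")
})
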