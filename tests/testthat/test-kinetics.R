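test_that("two-point line through 50% at t = 0 gives Ki = 5, P50 = 0", {
  fit <- fit_viability_line(c(0, 100), c(50, 100 * pnorm(-1)))
  expect_equal(fit$Ki, 5, tolerance = 1e-12)
  expect_equal(fit$sigma_d, 100, tolerance = 1e-9)
  expect_equal(fit$p50_d, 0, tolerance = 1e-9)
  expect_true(fit$flags$below_50_at_start || fit$p50_d == 0)
})

test_that("least squares is exact on noiseless probit-linear series", {
  s <- noiseless_series(6, 150, c(0, 30, 60, 90))
  fit <- fit_viability_line(s$time_d, s$germ_pct)
  expect_equal(fit$Ki, 6, tolerance = 1e-6)
  expect_equal(fit$sigma_d, 150, tolerance = 1e-6)
  expect_equal(fit$p50_d, 150, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("GLM agrees with least squares on noiseless mid-range data", {
  rec <- noiseless_records(6, 150, c(0, 30, 60, 90))
  g <- fit_viability_glm(rec)
  expect_equal(g$Ki, 6, tolerance = 1e-3)
  expect_equal(g$sigma_d, 150, tolerance = 1e-3 * 150)
  s <- noiseless_series(6, 150, c(0, 30, 60, 90))
  l <- fit_viability_line(s$time_d, s$germ_pct)
  expect_equal(g$Ki, l$Ki, tolerance = 1e-3)
  expect_equal(g$sigma_d, l$sigma_d, tolerance = 1e-3 * l$sigma_d)
})

test_that("0/100% correction policies behave as documented", {
  t <- c(0, 60, 120, 180)
  pct <- c(100, 90, 70, 40)
  fit <- fit_viability_line(t, pct)
  expect_equal(fit$n_points_used, 3L)
  expect_equal(nrow(fit$excluded_points), 1L)
  expect_match(fit$excluded_points$reason, "100%.*exclude")

  fitb <- fit_viability_line(t, pct, correction = "bartlett", n_seeds = rep(100, 4))
  expect_equal(fitb$n_points_used, 4L)
  # corrected value: (100 + 0.5)/(100 + 1) = 99.5049...%
  expect_error(fit_viability_line(t, pct, correction = "bartlett"), "n_seeds")
})

test_that("all-zero tail beyond the first zero is excluded as a dead-lot plateau", {
  t <- c(0, 50, 100, 150, 200)
  pct <- c(90, 40, 0, 0, 0)
  fit <- fit_viability_line(t, pct)
  expect_equal(sum(grepl("plateau", fit$excluded_points$reason)), 2L)
  # the first zero is excluded by the probit-domain policy, not the plateau rule
  expect_equal(sum(grepl("probit domain", fit$excluded_points$reason)), 1L)
  expect_equal(fit$n_points_used, 2L)
})

test_that("non-declining series yield infinite sigma and an undefined P50", {
  fit <- fit_viability_line(c(0, 50, 100), c(80, 85, 90))
  expect_true(is.infinite(fit$sigma_d))
  expect_true(fit$flags$non_declining)
  expect_error(p50(fit), "undefined")
})

test_that("insufficient usable points raise an informative error", {
  expect_error(fit_viability_line(c(0, 50), c(100, 40)), "insufficient data")
  expect_error(fit_viability_line(c(0, 0), c(80, 60)), "insufficient data")
})

test_that("p50 arithmetic, flags and extrapolation boundary", {
  s <- noiseless_series(6, 100, c(0, 40, 80, 120))
  fit <- fit_viability_line(s$time_d, s$germ_pct)
  expect_equal(as.numeric(p50(fit)), 100, tolerance = 1e-9)
  expect_false(attr(p50(fit), "extrapolated")) # 100 <= 120

  # P50 exactly at the last observation: flag cleared
  s2 <- noiseless_series(6.5, 200, c(0, 150, 300))
  f2 <- fit_viability_line(s2$time_d, s2$germ_pct)
  expect_equal(as.numeric(p50(f2)), 300, tolerance = 1e-9)
  expect_false(attr(p50(f2), "extrapolated"))

  # P50 beyond the data: flagged
  s3 <- noiseless_series(6.5, 200, c(0, 100, 200))
  f3 <- fit_viability_line(s3$time_d, s3$germ_pct)
  expect_true(attr(p50(f3), "extrapolated"))

  # lot starting below 50%
  s4 <- noiseless_series(4.5, 100, c(0, 40, 80))
  f4 <- fit_viability_line(s4$time_d, s4$germ_pct)
  expect_equal(as.numeric(p50(f4)), 0)
  expect_true(attr(p50(f4), "below_50_at_start"))
})

test_that("predict_germination inverts the fit and decreases in time", {
  s <- noiseless_series(6, 100, c(0, 40, 80, 120))
  fit <- fit_viability_line(s$time_d, s$germ_pct)
  expect_equal(predict_germination(fit, 0), inverse_probit(fit$Ki))
  expect_equal(predict_germination(fit, as.numeric(p50(fit))), 50, tolerance = 1e-9)
  expect_equal(predict_germination(fit, 200), 100 * pnorm(-1), tolerance = 1e-9)
  expect_true(all(diff(predict_germination(fit, seq(0, 300, 25))) < 0))
})

test_that("P50 scales with time units; Ki does not", {
  s <- noiseless_series(6.2, 180, c(0, 45, 90, 135))
  f1 <- fit_viability_line(s$time_d, s$germ_pct)
  for (c_scale in c(0.5, 3, 10)) {
    f2 <- fit_viability_line(s$time_d * c_scale, s$germ_pct)
    expect_equal(f2$Ki, f1$Ki, tolerance = 1e-9)
    expect_equal(f2$sigma_d, f1$sigma_d * c_scale, tolerance = 1e-9)
    expect_equal(f2$p50_d, f1$p50_d * c_scale, tolerance = 1e-9)
  }
})

test_that("with Ki fixed above 5, P50 strictly increases with sigma", {
  p50s <- vapply(c(50, 100, 200, 400, 800), function(sg) {
    s <- noiseless_series(6.3, sg, c(0, 30, 60, 90))
    fit_viability_line(s$time_d, s$germ_pct)$p50_d
  }, numeric(1))
  expect_true(all(diff(p50s) > 0))
})

test_that("GLM handles counts directly: consistency, flat lots, separation", {
  # near-deterministic counts at large n recover the truth within 0.5%
  rec <- noiseless_records(6, 150, c(0, 40, 80, 120, 160, 200), n_sown = 1e5)
  g <- fit_viability_glm(rec)
  expect_lt(abs(g$p50_d - 150) / 150, 0.005)

  flat <- data.frame(time_d = rep(c(0, 50, 100), each = 2), replicate = 1:2,
                     n_sown = 20, n_germ = 15)
  gf <- fit_viability_glm(flat)
  expect_true(is.infinite(gf$sigma_d))

  # all-or-nothing step in time: complete separation is flagged
  sep <- data.frame(time_d = rep(c(0, 10, 100, 110), each = 2), replicate = 1:2,
                    n_sown = 20, n_germ = rep(c(20, 20, 0, 0), each = 2))
  expect_warning(gs <- fit_viability_glm(sep), "separation")
  expect_true(gs$flags$separation)
})

test_that("GLM log-likelihood dominates the least-squares parameters", {
  set.seed(314)
  for (i in 1:10) {
    cfg <- lot_simulation_config(
      true_Ki = runif(1, 5.5, 6.5) + 0 * i, true_sigma_d = runif(1, 150, 350),
      schedule = seq(0, 300, by = 60), rng_seed = 100 + i
    )
    sim <- simulate_lot(cfg)
    g <- suppressWarnings(fit_viability_glm(sim$records))
    sm <- summarize_germination(sim$records)
    l <- tryCatch(fit_viability_line(sm$time_d, sm$mean_pct),
                  error = function(e) NULL)
    if (is.null(l) || is.infinite(l$sigma_d)) next
    ll_ls <- viability_loglik(sim$records, l$Ki, l$sigma_d)
    expect_gte(g$log_lik, ll_ls - 1e-6)
  }
})

test_that("bootstrap CI is deterministic given the seed and tight on clean data", {
  sim <- simulate_lot(lot_simulation_config(6.3, 250, c(0, 80, 160, 240, 320),
                                            rng_seed = 21))
  a <- bootstrap_p50_ci(sim$records, B = 300, seed = 99)
  b <- bootstrap_p50_ci(sim$records, B = 300, seed = 99)
  expect_identical(a[c("lower", "upper", "estimate")],
                   b[c("lower", "upper", "estimate")])
  d <- bootstrap_p50_ci(sim$records, B = 300, seed = 100)
  expect_false(identical(a$lower, d$lower))
  expect_lte(a$lower, a$estimate)
  expect_gte(a$upper, a$estimate)

  # identical replicates: resampling cannot move the fit
  clean <- noiseless_records(6, 150, c(0, 40, 80, 120), n_sown = 20)
  clean <- do.call(rbind, lapply(1:5, function(r) transform(clean, replicate = r)))
  clean$n_germ <- round(clean$n_germ)
  ci <- bootstrap_p50_ci(clean, B = 200, seed = 1)
  expect_lt(ci$upper - ci$lower, 1e-6)
})

test_that("bootstrap matches a replicate-mean refit with fit_viability_line", {
  # the vectorised fast path and the user-facing estimator are the same math:
  # a resample that reproduces the original replicates gives the same P50
  sim <- simulate_lot(lot_simulation_config(6.3, 250, c(0, 80, 160, 240),
                                            rng_seed = 3))
  sm <- summarize_germination(sim$records)
  fit <- fit_viability_line(sm$time_d, sm$mean_pct)
  ci <- bootstrap_p50_ci(sim$records, B = 500, seed = 5)
  expect_equal(ci$estimate, fit$p50_d, tolerance = 1e-12)
})

test_that("fit JSON serialization round-trips", {
  s <- noiseless_series(6, 150, c(0, 30, 60, 90))
  fit <- fit_viability_line(s$time_d, s$germ_pct)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "fit.json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_s3_class(back, "viability_fit")
  expect_equal(back$Ki, fit$Ki)
  expect_equal(back$sigma_d, fit$sigma_d)
  expect_equal(back$p50_d, fit$p50_d)
  expect_equal(back$method, fit$method)
})
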