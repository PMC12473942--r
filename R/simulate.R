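## Synthetic germination experiments, climate panels and isotherms with the
## statistical structure the estimators assume, for parameter-recovery and
## coverage studies. Every generator is bit-reproducible from its config
## seed; substreams are derived by a counter scheme so adding a lot never
## perturbs earlier lots.

# Deterministic substream seed: mixes a base seed with a counter, staying
# below 2^31 so set.seed() accepts it on every platform.
.substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 2147483647 + counter * 1103515245) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Configuration of one simulated seed-lot storage experiment
#'
#' Defaults mirror the standard germination test design: 5 replicates of 20
#' seeds at each sampling time.
#'
#' @param true_Ki true initial viability, probit units.
#' @param true_sigma_d true longevity, days per probit (> 0).
#' @param schedule sampling days (sorted, non-negative).
#' @param n_reps replicates per sampling time (>= 1; default 5).
#' @param n_sown seeds per replicate (>= 1; default 20).
#' @param rng_seed integer seed governing all draws for this lot.
#' @param overdispersion beta-binomial overdispersion rho in \[0, 1); 0
#'   (default) gives pure binomial sampling.
#' @return a `lot_simulation_config` list.
#' @export
lot_simulation_config <- function(true_Ki, true_sigma_d, schedule,
                                  n_reps = 5, n_sown = 20, rng_seed = 1L,
                                  overdispersion = 0) {
  if (true_sigma_d <= 0) stop("true_sigma_d must be positive")
  if (is.unsorted(schedule) || any(schedule < 0)) {
    stop("schedule must be sorted and non-negative")
  }
  if (n_reps < 1 || n_sown < 1) stop("n_reps and n_sown must be >= 1")
  if (overdispersion < 0 || overdispersion >= 1) {
    stop("overdispersion must lie in [0, 1)")
  }
  structure(list(true_Ki = true_Ki, true_sigma_d = true_sigma_d,
                 schedule = schedule, n_reps = as.integer(n_reps),
                 n_sown = as.integer(n_sown), rng_seed = as.integer(rng_seed),
                 overdispersion = overdispersion),
            class = "lot_simulation_config")
}

#' Simulate a germination storage experiment for one seed lot
#'
#' At each scheduled day `t` the germination probability is
#' `Phi((true_Ki - t/true_sigma_d) - 5)` — the probit viability line — and
#' each replicate draws `n_germ ~ Binomial(n_sown, p)` (or beta-binomial
#' when overdispersion is set).
#'
#' @param config a [lot_simulation_config()].
#' @param lot_id,regime_id labels stamped on the records.
#' @return list with `records` (a validated germination data frame) and
#'   `truth` (`Ki`, `sigma_d`, `p50_d`).
#' @examples
#' sim <- simulate_lot(lot_simulation_config(6.28, 300, c(0, 90, 180, 270, 360),
#'                                           rng_seed = 7))
#' head(sim$records)
#' sim$truth
#' @export
simulate_lot <- function(config, lot_id = "sim_lot", regime_id = "sim") {
  stopifnot(inherits(config, "lot_simulation_config"))
  k <- length(config$schedule)
  p <- stats::pnorm(config$true_Ki - config$schedule / config$true_sigma_d - 5)
  records <- .with_seed(config$rng_seed, {
    n_germ <- integer(0)
    for (j in seq_len(k)) {
      if (config$overdispersion > 0) {
        rho <- config$overdispersion
        a <- p[j] * (1 - rho) / rho
        b <- (1 - p[j]) * (1 - rho) / rho
        pr <- stats::rbeta(config$n_reps, a, b)
        n_germ <- c(n_germ, stats::rbinom(config$n_reps, config$n_sown, pr))
      } else {
        n_germ <- c(n_germ, stats::rbinom(config$n_reps, config$n_sown, p[j]))
      }
    }
    data.frame(
      lot_id = lot_id, regime_id = regime_id,
      time_d = rep(config$schedule, each = config$n_reps),
      replicate = rep(seq_len(config$n_reps), times = k),
      n_sown = config$n_sown, n_germ = n_germ
    )
  })
  truth <- list(Ki = config$true_Ki, sigma_d = config$true_sigma_d,
                p50_d = config$true_sigma_d * (config$true_Ki - 5))
  list(records = records, truth = truth)
}

#' Configuration of a simulated climate-longevity panel
#'
#' Defaults emulate a small panel of poplar seed lots whose dry-storage
#' half-lives rise with collection-site annual temperature: covariate
#' ranges of roughly 8-14 degC, 60-930 mm and 100-2200 m, a strong built-in
#' temperature effect, and lot-level noise.
#'
#' @param n_lots number of lots (>= 3).
#' @param temp_range,precip_range,elev_range covariate ranges (uniform draws).
#' @param baseline_p50 intercept of the true P50 surface, days.
#' @param effects named vector of slopes of expected P50 per covariate unit
#'   (`temp`, `precip`, `elev`).
#' @param noise_sd SD of lot-level normal deviations of true P50, days (>= 0).
#' @param rng_seed integer seed.
#' @return a `panel_simulation_config` list.
#' @export
panel_simulation_config <- function(n_lots = 6,
                                    temp_range = c(8, 14),
                                    precip_range = c(60, 930),
                                    elev_range = c(100, 2200),
                                    baseline_p50 = -1460,
                                    effects = c(temp = 210, precip = 0, elev = 0),
                                    noise_sd = 150,
                                    rng_seed = 1L) {
  if (n_lots < 3) stop("n_lots must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  effects <- effects[c("temp", "precip", "elev")]
  effects[is.na(effects)] <- 0
  names(effects) <- c("temp", "precip", "elev")
  structure(list(n_lots = as.integer(n_lots), temp_range = temp_range,
                 precip_range = precip_range, elev_range = elev_range,
                 baseline_p50 = baseline_p50, effects = effects,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "panel_simulation_config")
}

#' Simulate a climate panel with known longevity-covariate structure
#'
#' Covariates are drawn uniformly over their ranges; the true half-life is
#' `baseline + effects.temp*T + effects.precip*P + effects.elev*E +
#' Normal(0, noise_sd)`, floored at 1 d to avoid non-physical values.
#'
#' @param config a [panel_simulation_config()].
#' @return data frame with `lot_id`, `annual_temp_C`, `annual_precip_mm`,
#'   `elevation_m`, `true_p50_d`.
#' @export
simulate_climate_panel <- function(config) {
  stopifnot(inherits(config, "panel_simulation_config"))
  .with_seed(config$rng_seed, {
    n <- config$n_lots
    temp <- stats::runif(n, config$temp_range[1], config$temp_range[2])
    precip <- stats::runif(n, config$precip_range[1], config$precip_range[2])
    elev <- stats::runif(n, config$elev_range[1], config$elev_range[2])
    p50 <- config$baseline_p50 + config$effects["temp"] * temp +
      config$effects["precip"] * precip + config$effects["elev"] * elev +
      stats::rnorm(n, 0, config$noise_sd)
    data.frame(
      lot_id = sprintf("lot%02d", seq_len(n)),
      annual_temp_C = temp, annual_precip_mm = precip, elevation_m = elev,
      true_p50_d = pmax(p50, 1)
    )
  })
}

#' Simulate water-sorption isotherm measurements
#'
#' Generates replicate equilibrium moisture contents at evenly spaced water
#' activities from a smooth monotone truth curve
#' `mc(a_w) = c0 + c1*a_w + c3*a_w^3` plus additive normal noise. The
#' default coefficients give a curve rising from about 3% MC at a_w 0.15 to
#' about 26% above water, the shape typical of dry orthodox seeds.
#'
#' @param n_levels number of distinct water activities (>= 2).
#' @param aw_range range of water activities (default 0.15-1, the span of
#'   saturated-salt equilibration series).
#' @param n_reps replicates per level (default 3).
#' @param coef numeric `c(c0, c1, c3)` of the truth curve.
#' @param noise_sd SD of additive measurement noise, percentage points.
#' @param rng_seed integer seed.
#' @return list with `points` (data frame `a_w`, `replicate`, `mc_pct_fw`)
#'   and `truth` (the generating function of a_w).
#' @export
simulate_isotherm <- function(n_levels = 5, aw_range = c(0.15, 1),
                              n_reps = 3, coef = c(2, 6, 18),
                              noise_sd = 0, rng_seed = 1L) {
  if (n_levels < 2) stop("need >= 2 water-activity levels")
  if (coef[2] < 0 || coef[3] < 0) {
    stop("truth curve must be monotone: c1 and c3 must be >= 0")
  }
  truth <- function(aw) coef[1] + coef[2] * aw + coef[3] * aw^3
  aw <- seq(aw_range[1], aw_range[2], length.out = n_levels)
  points <- .with_seed(rng_seed, {
    data.frame(
      a_w = rep(aw, each = n_reps),
      replicate = rep(seq_len(n_reps), times = n_levels),
      mc_pct_fw = pmax(0.1, rep(truth(aw), each = n_reps) +
                         stats::rnorm(n_levels * n_reps, 0, noise_sd))
    )
  })
  list(points = points, truth = truth)
}

#' Parameter-recovery experiment over a grid of simulation configurations
#'
#' For each configuration: simulate `n_sims` lots, fit the chosen estimator,
#' and compare the estimated P50 (and Ki, sigma) with the truth. Optionally
#' also measures bootstrap confidence-interval coverage. Cells where the
#' estimator fails on more than 20% of simulated lots are flagged, not
#' fatal.
#'
#' @param configs list of [lot_simulation_config()] objects (the grid).
#' @param estimator `"glm"` (binomial probit regression) or `"ls"`
#'   (least squares on probit replicate means).
#' @param n_sims simulated lots per cell (>= 100).
#' @param rng_seed integer master seed; per-lot substreams are derived
#'   deterministically from it.
#' @param ci if `TRUE`, also run [bootstrap_p50_ci()] per simulated lot and
#'   report coverage of the true P50.
#' @param B bootstrap resamples when `ci = TRUE`.
#' @param level CI level when `ci = TRUE`.
#' @return data frame with one row per cell: the truth, `n_fit`,
#'   `failure_rate`, `median_bias_p50`, `median_rel_err_p50`,
#'   `rel_rmse_p50`, `median_rel_err_ki`, `median_rel_err_sigma`,
#'   `coverage` (NA unless `ci`), `flagged`.
#' @export
recovery_experiment <- function(configs, estimator = c("glm", "ls"),
                                n_sims = 500, rng_seed = 1L, ci = FALSE,
                                B = 1000, level = 0.95) {
  estimator <- match.arg(estimator)
  if (n_sims < 100) stop("n_sims must be >= 100")
  if (inherits(configs, "lot_simulation_config")) configs <- list(configs)

  rows <- lapply(seq_along(configs), function(cell) {
    cfg <- configs[[cell]]
    true_p50 <- cfg$true_sigma_d * (cfg$true_Ki - 5)
    est <- matrix(NA_real_, n_sims, 3,
                  dimnames = list(NULL, c("p50", "Ki", "sigma")))
    covered <- rep(NA, n_sims)
    for (s in seq_len(n_sims)) {
      sub <- lot_simulation_config(
        cfg$true_Ki, cfg$true_sigma_d, cfg$schedule, cfg$n_reps, cfg$n_sown,
        rng_seed = .substream_seed(rng_seed, (cell - 1L) * n_sims + s),
        overdispersion = cfg$overdispersion
      )
      sim <- simulate_lot(sub)
      fit <- tryCatch({
        if (estimator == "glm") {
          suppressWarnings(fit_viability_glm(sim$records))
        } else {
          sm <- summarize_germination(sim$records)
          fit_viability_line(sm$time_d, sm$mean_pct,
                             n_seeds = sm$n_reps * cfg$n_sown)
        }
      }, error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$sigma_d) && is.finite(fit$p50_d)) {
        est[s, ] <- c(fit$p50_d, fit$Ki, fit$sigma_d)
      }
      if (isTRUE(ci)) {
        cires <- tryCatch(
          bootstrap_p50_ci(sim$records, B = B, level = level,
                           seed = .substream_seed(rng_seed,
                                                  1000000L + (cell - 1L) * n_sims + s)),
          error = function(e) NULL
        )
        if (!is.null(cires)) {
          covered[s] <- cires$lower <= true_p50 && true_p50 <= cires$upper
        }
      }
    }
    ok <- !is.na(est[, "p50"])
    rel <- (est[ok, "p50"] - true_p50) / true_p50
    data.frame(
      true_Ki = cfg$true_Ki, true_sigma_d = cfg$true_sigma_d,
      true_p50 = true_p50, n_sims = n_sims, n_fit = sum(ok),
      failure_rate = 1 - mean(ok),
      median_bias_p50 = stats::median(est[ok, "p50"]) - true_p50,
      median_rel_err_p50 = stats::median(abs(rel)),
      rel_rmse_p50 = sqrt(mean(rel^2)),
      median_rel_err_ki = stats::median(abs(est[ok, "Ki"] - cfg$true_Ki) / cfg$true_Ki),
      median_rel_err_sigma = stats::median(abs(est[ok, "sigma"] - cfg$true_sigma_d) /
                                             cfg$true_sigma_d),
      coverage = if (isTRUE(ci)) mean(covered, na.rm = TRUE) else NA_real_,
      flagged = (1 - mean(ok)) > 0.2
    )
  })
  do.call(rbind, rows)
}
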