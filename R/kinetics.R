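## Probit viability-loss kinetics: v = Ki - p/sigma, with v in probit units
## (NED+5), p days of storage, Ki initial viability, sigma days to lose one
## probit. P50 = sigma * (Ki - 5) is the time to 50% germination.

#' Construct a viability fit object
#'
#' Internal constructor shared by the least-squares and GLM estimators.
#' @noRd
new_viability_fit <- function(Ki, sigma_d, method, n_points_used,
                              r_squared = NA_real_, excluded_points = NULL,
                              correction = NA_character_, log_lik = NA_real_,
                              t_max = NA_real_, flags = list()) {
  flags <- utils::modifyList(
    list(non_declining = FALSE, below_50_at_start = FALSE,
         extrapolated = FALSE, separation = FALSE),
    flags
  )
  if (is.null(excluded_points)) {
    excluded_points <- data.frame(time_d = numeric(0), germ_pct = numeric(0),
                                  reason = character(0))
  }
  p50_d <- if (flags$non_declining || is.infinite(sigma_d)) {
    NA_real_
  } else if (Ki < 5) {
    0
  } else {
    sigma_d * (Ki - 5)
  }
  if (isTRUE(Ki < 5)) flags$below_50_at_start <- TRUE
  if (is.finite(p50_d) && is.finite(t_max) && p50_d > t_max) {
    flags$extrapolated <- TRUE
  }
  structure(
    list(Ki = Ki, sigma_d = sigma_d, p50_d = p50_d, method = method,
         n_points_used = n_points_used, r_squared = r_squared,
         excluded_points = excluded_points, correction = correction,
         log_lik = log_lik, t_max = t_max, flags = flags),
    class = "viability_fit"
  )
}

#' @export
print.viability_fit <- function(x, ...) {
  cat("Viability fit (", x$method, ")\n", sep = "")
  cat(sprintf("  Ki    = %.4f probits\n", x$Ki))
  if (is.infinite(x$sigma_d)) {
    cat("  sigma = Inf (no decline detected); P50 undefined\n")
  } else {
    cat(sprintf("  sigma = %.4f d/probit\n", x$sigma_d))
    cat(sprintf("  P50   = %.2f d%s\n", x$p50_d,
                if (x$flags$extrapolated) " (extrapolated beyond data)" else ""))
  }
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 (probit scale) = %.4f\n", x$r_squared))
  if (!is.na(x$log_lik)) cat(sprintf("  log-likelihood = %.3f\n", x$log_lik))
  if (nrow(x$excluded_points)) {
    cat("  excluded points:\n")
    for (i in seq_len(nrow(x$excluded_points))) {
      cat(sprintf("    t = %g d (%g%%): %s\n", x$excluded_points$time_d[i],
                  x$excluded_points$germ_pct[i], x$excluded_points$reason[i]))
    }
  }
  if (x$flags$below_50_at_start) cat("  note: initial viability below 50%; P50 set to 0\n")
  if (x$flags$separation) cat("  warning: complete separation; estimates at search boundary\n")
  invisible(x)
}

# Closed-form OLS of v on t. Returns intercept, slope, r2. Used by both the
# user-facing least-squares fit and the vectorised bootstrap fast path so the
# two can never disagree.
.probit_line_ols <- function(time_d, v, w = NULL) {
  if (is.null(w)) w <- rep(1, length(time_d))
  sw <- sum(w)
  mx <- sum(w * time_d) / sw
  my <- sum(w * v) / sw
  sxx <- sum(w * (time_d - mx)^2)
  sxy <- sum(w * (time_d - mx) * (v - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- v - (intercept + slope * time_d)
  ss_res <- sum(w * res^2)
  ss_tot <- sum(w * (v - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(intercept = intercept, slope = slope, r_squared = r2)
}

# Split a germination series into usable and excluded points under the
# dead-lot-plateau rule and the 0/100% correction policy. Works on
# percentages; `n_seeds` (pooled seeds behind each percentage) is required
# for the Bartlett correction.
.prepare_probit_points <- function(time_d, germ_pct, correction, n_seeds) {
  ord <- order(time_d)
  time_d <- time_d[ord]; germ_pct <- germ_pct[ord]
  if (!is.null(n_seeds)) n_seeds <- n_seeds[ord]
  reason <- rep(NA_character_, length(time_d))

  # all-zero tail beyond the first zero is an uninformative dead-lot plateau
  zero <- which(germ_pct == 0)
  if (length(zero) >= 2) {
    first0 <- zero[1]
    tail0 <- zero[zero > first0]
    tail0 <- tail0[vapply(tail0, function(i) all(germ_pct[first0:i] == 0), logical(1))]
    reason[tail0] <- "dead-lot plateau (all-zero tail)"
  }

  extreme <- is.na(reason) & (germ_pct <= 0 | germ_pct >= 100)
  pct_use <- germ_pct
  if (correction == "exclude") {
    reason[extreme] <- ifelse(germ_pct[extreme] <= 0,
                              "0% outside probit domain (policy: exclude)",
                              "100% outside probit domain (policy: exclude)")
  } else { # bartlett
    if (any(extreme)) {
      if (is.null(n_seeds) || anyNA(n_seeds[extreme])) {
        stop("correction = \"bartlett\" needs `n_seeds` (pooled seed count ",
             "behind each percentage) for 0%/100% points")
      }
      r <- round(germ_pct[extreme] / 100 * n_seeds[extreme])
      pct_use[extreme] <- 100 * (r + 0.5) / (n_seeds[extreme] + 1)
    }
  }

  keep <- is.na(reason)
  list(
    time_d = time_d[keep], germ_pct = pct_use[keep],
    keep_idx = ord[keep],
    excluded = data.frame(time_d = time_d[!keep], germ_pct = germ_pct[!keep],
                          reason = reason[!keep])
  )
}

#' Fit the probit viability-loss line by least squares
#'
#' Regresses probit-transformed germination percentages on storage time:
#' `v = Ki - t/sigma`. The intercept estimates the initial viability `Ki`
#' (probit units), minus the reciprocal slope estimates `sigma` (days to
#' lose one probit), and the half-life is `P50 = sigma * (Ki - 5)`.
#' One point per storage time (typically the replicate-mean percentage) is
#' the intended input; a replicate-level weighted fit is available through
#' `weights`.
#'
#' Exact 0% and 100% observations have no probit value. Two policies are
#' offered: `"exclude"` (default) drops them and records the exclusion, and
#' `"bartlett"` replaces the pooled count r of n with (r + 0.5)/(n + 1),
#' which requires `n_seeds`. Independently of the policy, all-zero time
#' points beyond the first zero are always dropped as a dead-lot plateau.
#'
#' @param time_d numeric vector of storage times in days (>= 0).
#' @param germ_pct numeric vector of germination percentages in \[0, 100\].
#' @param correction policy for 0%/100% points: `"exclude"` or `"bartlett"`.
#' @param n_seeds optional pooled seed count behind each percentage
#'   (required by the Bartlett correction).
#' @param weights optional non-negative weights for a replicate-level fit.
#' @return an object of class `viability_fit` with elements `Ki`, `sigma_d`,
#'   `p50_d`, `method`, `n_points_used`, `r_squared` (probit scale),
#'   `excluded_points`, `correction`, `t_max` and `flags`
#'   (`non_declining`, `below_50_at_start`, `extrapolated`).
#'   Non-declining series get `sigma_d = Inf` and an undefined P50.
#' @examples
#' t <- c(0, 90, 180, 270)
#' pct <- inverse_probit(6 - t / 150)
#' fit_viability_line(t, pct) # recovers Ki = 6, sigma = 150, P50 = 150
#' @export
fit_viability_line <- function(time_d, germ_pct,
                               correction = c("exclude", "bartlett"),
                               n_seeds = NULL, weights = NULL) {
  correction <- match.arg(correction)
  if (length(time_d) != length(germ_pct)) {
    stop("`time_d` and `germ_pct` must have the same length")
  }
  if (any(time_d < 0)) stop("storage times must be non-negative")
  if (any(germ_pct < 0 | germ_pct > 100)) {
    stop("germination percentages must lie in [0, 100]")
  }
  if (!is.null(weights) && length(weights) != length(time_d)) {
    stop("`weights` must match the data length")
  }

  pts <- .prepare_probit_points(time_d, germ_pct, correction, n_seeds)
  if (length(pts$time_d) < 2 || length(unique(pts$time_d)) < 2) {
    stop("insufficient data: need >= 2 usable points at distinct times after ",
         "the 0/100% policy; excluded: ",
         if (nrow(pts$excluded)) paste(sprintf("t=%g (%s)", pts$excluded$time_d,
                                               pts$excluded$reason),
                                       collapse = "; ")
         else "none")
  }

  w <- if (is.null(weights)) NULL else weights[pts$keep_idx]

  v <- probit(pts$germ_pct)
  ols <- .probit_line_ols(pts$time_d, v, w)

  if (ols$slope >= 0) {
    return(new_viability_fit(
      Ki = ols$intercept, sigma_d = Inf, method = "probit-least-squares",
      n_points_used = length(pts$time_d), r_squared = ols$r_squared,
      excluded_points = pts$excluded, correction = correction,
      t_max = max(pts$time_d), flags = list(non_declining = TRUE)
    ))
  }
  new_viability_fit(
    Ki = ols$intercept, sigma_d = -1 / ols$slope,
    method = "probit-least-squares", n_points_used = length(pts$time_d),
    r_squared = ols$r_squared, excluded_points = pts$excluded,
    correction = correction, t_max = max(pts$time_d)
  )
}

#' Binomial log-likelihood of a viability line given germination counts
#'
#' Evaluates the binomial log-likelihood of the probit viability-loss model
#' with parameters (`Ki`, `sigma_d`) on replicate-level germination counts.
#' Used to compare estimators: the GLM fit maximises exactly this function.
#' Fractional counts (e.g. noiseless expected counts) are supported through
#' the gamma-function form of the binomial coefficient.
#'
#' @param records data frame with columns `time_d`, `n_sown`, `n_germ`.
#' @param Ki initial viability in probit units.
#' @param sigma_d days per probit; `Inf` means a flat line at `Ki`.
#' @return the log-likelihood (a scalar).
#' @export
viability_loglik <- function(records, Ki, sigma_d) {
  .check_columns(records, c("time_d", "n_sown", "n_germ"))
  v <- Ki - if (is.infinite(sigma_d)) 0 else records$time_d / sigma_d
  p <- stats::pnorm(v - 5)
  p <- pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
  k <- records$n_germ; n <- records$n_sown
  sum(lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
        k * log(p) + (n - k) * log1p(-p))
}

#' Fit the viability-loss model by binomial probit regression
#'
#' Maximum-likelihood estimation of the same line as [fit_viability_line()],
#' but on raw replicate counts with a probit link:
#' `Phi^-1(p) = (Ki - 5) - t/sigma`. Because the likelihood is defined on
#' counts, 0/20 and 20/20 observations need no correction policy.
#'
#' @param records data frame of replicate germination tests for one seed lot
#'   and storage regime, with columns `time_d`, `n_sown`, `n_germ`
#'   (additional columns are ignored). Fractional counts are accepted (used
#'   by noiseless consistency checks).
#' @return a `viability_fit` (method `"binomial-glm"`) carrying the
#'   log-likelihood at the optimum. Complete separation (an all-or-nothing
#'   step in time) is flagged via `flags$separation`, with estimates at the
#'   boundary the IRLS search reached. A zero slope yields `sigma_d = Inf`.
#' @examples
#' sim <- simulate_lot(lot_simulation_config(true_Ki = 6, true_sigma_d = 150,
#'                                           schedule = c(0, 60, 120, 180),
#'                                           rng_seed = 42))
#' fit_viability_glm(sim$records)
#' @export
fit_viability_glm <- function(records) {
  .check_columns(records, c("time_d", "n_sown", "n_germ"))
  if (any(records$n_sown <= 0)) stop("`n_sown` must be positive")
  if (any(records$n_germ < 0 | records$n_germ > records$n_sown)) {
    stop("`n_germ` must lie in [0, n_sown]")
  }
  if (length(unique(records$time_d)) < 2) {
    stop("insufficient data: need >= 2 distinct storage times")
  }

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(n_germ, n_sown - n_germ) ~ time_d,
               family = stats::binomial(link = "probit"), data = records),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("non-integer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) separation <- TRUE
  b <- stats::coef(fit)
  Ki <- unname(b[1]) + 5
  slope <- unname(b[2])
  if (separation) {
    warning("complete separation (or non-convergence): estimates are at the ",
            "boundary the IRLS search reached; interpret with care")
  }

  sigma_d <- if (slope >= -1e-12) Inf else -1 / slope
  ll <- viability_loglik(records, Ki, sigma_d)
  new_viability_fit(
    Ki = Ki, sigma_d = sigma_d, method = "binomial-glm",
    n_points_used = length(unique(records$time_d)), log_lik = ll,
    t_max = max(records$time_d),
    flags = list(separation = separation,
                 non_declining = is.infinite(sigma_d))
  )
}

#' Half-life P50 of a fitted viability line
#'
#' Returns the storage time at which viability reaches 5 probits (50%
#' germination): `P50 = sigma * (Ki - 5)`. A lot starting below 50%
#' germination (`Ki < 5`) gets P50 = 0 with the `below_50_at_start`
#' attribute set; a P50 beyond the last observed time carries the
#' `extrapolated` attribute.
#'
#' @param fit a `viability_fit`.
#' @return P50 in days, with logical attributes `extrapolated` and
#'   `below_50_at_start`.
#' @export
p50 <- function(fit) {
  stopifnot(inherits(fit, "viability_fit"))
  if (is.infinite(fit$sigma_d)) {
    stop("P50 is undefined: sigma is infinite (no viability decline detected)")
  }
  structure(fit$p50_d,
            extrapolated = fit$flags$extrapolated,
            below_50_at_start = fit$flags$below_50_at_start)
}

#' Predicted germination percentage at a storage time
#'
#' Evaluates the fitted viability line: `inverse_probit(Ki - t/sigma)`.
#' Strictly decreasing in `t` for declining lots.
#'
#' @param fit a `viability_fit` with finite sigma.
#' @param t storage time(s) in days, >= 0.
#' @return germination percentage(s).
#' @export
predict_germination <- function(fit, t) {
  stopifnot(inherits(fit, "viability_fit"))
  if (any(t < 0)) stop("`t` must be non-negative")
  if (is.infinite(fit$sigma_d)) {
    return(inverse_probit(rep(fit$Ki, length(t))))
  }
  inverse_probit(fit$Ki - t / fit$sigma_d)
}

# Vectorised least-squares probit-line refits for B bootstrap resamples.
# V is a B x k matrix of probit viabilities (NA = excluded point); returns
# the B P50 values (Inf for non-declining resamples, NA for unfittable ones).
.p50_from_probit_matrix <- function(V, times) {
  B <- nrow(V); k <- ncol(V)
  p50s <- rep(NA_real_, B)
  complete <- !rowSums(is.na(V))
  if (any(complete)) {
    tc <- times - mean(times)
    sxx <- sum(tc^2)
    Vc <- V[complete, , drop = FALSE]
    my <- rowMeans(Vc)
    slope <- as.vector(Vc %*% tc) / sxx
    Ki <- my - slope * mean(times)
    p <- ifelse(slope >= 0, Inf, ifelse(Ki < 5, 0, -(Ki - 5) / slope))
    p50s[complete] <- p
  }
  partial <- which(!complete)
  for (b in partial) {
    ok <- !is.na(V[b, ])
    if (sum(ok) < 2 || length(unique(times[ok])) < 2) next
    o <- .probit_line_ols(times[ok], V[b, ok])
    p50s[b] <- if (o$slope >= 0) Inf else if (o$intercept < 5) 0 else
      -(o$intercept - 5) / o$slope
  }
  p50s
}

#' Bootstrap confidence interval for P50
#'
#' Nonparametric bootstrap for the half-life of a seed lot: replicates are
#' resampled with replacement within each storage time, the probit
#' least-squares line is refitted to the resampled replicate-mean
#' percentages (same estimator and 0/100% policy as
#' [fit_viability_line()]), and a percentile interval is taken over the
#' resampled P50s. Resamples whose line does not decline contribute
#' P50 = +Inf (the lot outlives the record); resamples with fewer than two
#' usable time points count as failures, and a failure rate above 20%
#' aborts with an error.
#'
#' @param records replicate-level data frame with columns `time_d`,
#'   `replicate`, `n_sown`, `n_germ` for one lot and regime.
#' @param B number of bootstrap resamples (>= 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the same seed reproduces the interval exactly.
#' @param correction 0/100% policy passed to the refits.
#' @return list of class `p50_ci`: `estimate`, `lower`, `upper`, `level`,
#'   `B`, `n_failed`, `seed`.
#' @export
bootstrap_p50_ci <- function(records, B = 1000, level = 0.95, seed = 1L,
                             correction = c("exclude", "bartlett")) {
  correction <- match.arg(correction)
  .check_columns(records, c("time_d", "replicate", "n_sown", "n_germ"))
  if (B < 100) stop("`B` must be at least 100")

  times <- sort(unique(records$time_d))
  k <- length(times)
  if (k < 2) stop("need >= 2 distinct storage times")
  pct_by_time <- lapply(times, function(tt) {
    r <- records[records$time_d == tt, ]
    list(pct = 100 * r$n_germ / r$n_sown, n = r$n_sown)
  })

  means <- vapply(pct_by_time, function(x) mean(x$pct), numeric(1))
  nsum <- vapply(pct_by_time, function(x) sum(x$n), numeric(1))
  point <- fit_viability_line(times, means, correction = correction,
                              n_seeds = nsum)
  if (is.infinite(point$sigma_d)) {
    stop("point estimate has infinite sigma; P50 interval undefined")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # B x k matrices of resampled replicate-mean percentages and pooled counts
  M <- matrix(NA_real_, B, k)
  Npool <- matrix(NA_real_, B, k)
  Rpool <- matrix(NA_real_, B, k)
  for (j in seq_len(k)) {
    pct <- pct_by_time[[j]]$pct
    nn <- pct_by_time[[j]]$n
    m <- length(pct)
    idx <- matrix(sample.int(m, B * m, replace = TRUE), B, m)
    M[, j] <- rowMeans(matrix(pct[idx], B, m))
    Npool[, j] <- rowSums(matrix(nn[idx], B, m))
    Rpool[, j] <- rowSums(matrix((pct * nn / 100)[idx], B, m))
  }

  # dead-lot plateau: within each resample, drop every zero after the first
  zeroM <- M == 0
  multi0 <- which(rowSums(zeroM) >= 2)
  for (b in multi0) {
    z <- which(zeroM[b, ])
    first0 <- z[1]
    later <- z[z > first0]
    later <- later[vapply(later, function(j) all(zeroM[b, first0:j]), logical(1))]
    M[b, later] <- NA
  }

  extreme <- !is.na(M) & (M <= 0 | M >= 100)
  if (correction == "exclude") {
    M[extreme] <- NA
  } else {
    r <- round(Rpool[extreme])
    M[extreme] <- 100 * (r + 0.5) / (Npool[extreme] + 1)
  }

  V <- M
  ok <- !is.na(M)
  V[ok] <- probit(M[ok])
  p50s <- .p50_from_probit_matrix(V, times)

  n_failed <- sum(is.na(p50s))
  if (n_failed / B > 0.2) {
    stop(sprintf("bootstrap failure rate %.1f%% exceeds 20%%: data too sparse",
                 100 * n_failed / B))
  }
  qs <- stats::quantile(p50s[!is.na(p50s)],
                        probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(
    list(estimate = point$p50_d, lower = qs[1], upper = qs[2],
         level = level, B = B, n_failed = n_failed, seed = as.integer(seed)),
    class = "p50_ci"
  )
}

#' @export
print.p50_ci <- function(x, ...) {
  cat(sprintf("P50 = %.1f d, %g%% bootstrap CI [%.1f, %.1f] (B = %d, %d failed)\n",
              x$estimate, 100 * x$level, x$lower, x$upper, x$B, x$n_failed))
  invisible(x)
}

#' Serialize a viability fit to JSON
#'
#' @param fit a `viability_fit`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "viability_fit"))
  out <- fit
  class(out) <- NULL
  out$sigma_d <- if (is.infinite(out$sigma_d)) "Inf" else out$sigma_d
  out$format_version <- "1"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a viability fit from JSON
#'
#' @param path file written by [write_fit_json()].
#' @return a `viability_fit`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$format_version <- NULL
  if (identical(x$sigma_d, "Inf")) x$sigma_d <- Inf
  if (is.null(x$excluded_points) || length(x$excluded_points) == 0) {
    x$excluded_points <- data.frame(time_d = numeric(0), germ_pct = numeric(0),
                                    reason = character(0))
  }
  x$p50_d <- if (is.null(x$p50_d)) NA_real_ else x$p50_d
  structure(x, class = "viability_fit")
}
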