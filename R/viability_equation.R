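## The seed viability equation: log10 sigma = K_E - C_W*log10(MC) - C_H*T
## - C_Q*T^2, with MC in % fresh weight and T in degC. K_E and C_W are
## species moisture constants; C_H and C_Q are temperature constants.

#' Construct a set of viability-equation constants
#'
#' @param K_E species moisture intercept (log10 days).
#' @param C_W moisture coefficient, per log10(% MC fresh weight).
#' @param C_H linear temperature coefficient, per degC.
#' @param C_Q quadratic temperature coefficient, per degC^2.
#' @return object of class `viability_constants`. Physically implausible
#'   values (`C_W <= 0`, `C_Q < 0`) are accepted with a warning, never a
#'   hard error.
#' @examples
#' viability_constants(K_E = 9, C_W = 5, C_H = 0.033, C_Q = 0.0005)
#' @export
viability_constants <- function(K_E, C_W, C_H, C_Q) {
  vals <- c(K_E = K_E, C_W = C_W, C_H = C_H, C_Q = C_Q)
  if (any(!is.finite(vals))) stop("all constants must be finite numbers")
  if (C_W <= 0) warning("C_W <= 0: sigma would not decrease with moisture; ",
                        "check the parameter set")
  if (C_Q < 0) warning("C_Q < 0 is physically unusual; check the parameter set")
  structure(list(K_E = K_E, C_W = C_W, C_H = C_H, C_Q = C_Q,
                 log_base = 10, mc_basis = "fresh"),
            class = "viability_constants")
}

#' @export
print.viability_constants <- function(x, ...) {
  cat("Viability-equation constants (log10, MC % fresh weight):\n")
  cat(sprintf("  K_E = %g, C_W = %g, C_H = %g, C_Q = %g\n",
              x$K_E, x$C_W, x$C_H, x$C_Q))
  invisible(x)
}

.check_condition <- function(mc_pct_fw, temperature_C) {
  if (any(mc_pct_fw <= 0 | mc_pct_fw >= 100)) {
    stop("moisture content must lie strictly between 0 and 100% fresh weight")
  }
  if (any(!is.finite(temperature_C))) stop("temperature must be finite")
}

#' Predict seed longevity sigma from storage conditions
#'
#' Evaluates the viability equation:
#' `sigma = 10^(K_E - C_W*log10(MC) - C_H*T - C_Q*T^2)` days per probit.
#'
#' @param constants a [viability_constants()] object.
#' @param mc_pct_fw moisture content, % fresh-weight basis, in (0, 100).
#' @param temperature_C storage temperature in degC.
#' @return sigma in days per probit (strictly positive); vectorised over
#'   conditions.
#' @examples
#' k <- viability_constants(9, 5, 0.033, 0.0005)
#' predict_sigma(k, mc_pct_fw = 10, temperature_C = 20) # 10^3.14
#' @export
predict_sigma <- function(constants, mc_pct_fw, temperature_C) {
  stopifnot(inherits(constants, "viability_constants"))
  .check_condition(mc_pct_fw, temperature_C)
  ls <- constants$K_E - constants$C_W * log10(mc_pct_fw) -
    constants$C_H * temperature_C - constants$C_Q * temperature_C^2
  over <- abs(ls) > 300
  if (any(over)) {
    stop(sprintf("log10(sigma) = %g overflows the representable range at MC = %g%%, T = %g degC",
                 ls[which(over)[1]], mc_pct_fw[which(over)[1]],
                 temperature_C[which(over)[1]]))
  }
  10^ls
}

#' Longevity ratio between two storage conditions
#'
#' `sigma(A) / sigma(B)` under the viability equation. The species
#' intercept `K_E` cancels, so the ratio depends only on `C_W`, `C_H`,
#' `C_Q` and the two conditions — convenient for questions like "how much
#' longer do these seeds live in the dry room than at ambient?".
#'
#' @param constants a [viability_constants()] object.
#' @param condA,condB lists with elements `mc_pct_fw` and `temperature_C`.
#' @return the ratio sigma(A)/sigma(B).
#' @export
longevity_ratio <- function(constants, condA, condB) {
  stopifnot(inherits(constants, "viability_constants"))
  .check_condition(condA$mc_pct_fw, condA$temperature_C)
  .check_condition(condB$mc_pct_fw, condB$temperature_C)
  10^(constants$C_W * log10(condB$mc_pct_fw / condA$mc_pct_fw) +
        constants$C_H * (condB$temperature_C - condA$temperature_C) +
        constants$C_Q * (condB$temperature_C^2 - condA$temperature_C^2))
}

#' Fit the moisture constants of the viability equation
#'
#' Least squares of `log10(sigma)` on `log10(MC)` for observations at a
#' common temperature: the slope estimates `-C_W`; the intercept is the
#' temperature-absorbed `K_E* = K_E - C_H*T - C_Q*T^2`. The full `K_E` is
#' recoverable only when the temperature and the temperature constants are
#' supplied.
#'
#' @param mc_pct_fw moisture contents (% fresh weight), >= 2 distinct values.
#' @param sigma_d observed sigma values (days per probit), same length.
#' @param temperature_C optional common temperature of the observations.
#' @param C_H,C_Q optional temperature constants used (with
#'   `temperature_C`) to recover the full `K_E`.
#' @return list with `C_W`, `K_E_star` (temperature-absorbed intercept),
#'   `K_E` (or `NA` when not recoverable), `r_squared`, `rss`, `n`.
#' @export
fit_moisture_constants <- function(mc_pct_fw, sigma_d, temperature_C = NULL,
                                   C_H = NULL, C_Q = NULL) {
  if (length(mc_pct_fw) != length(sigma_d)) stop("input lengths differ")
  if (length(unique(mc_pct_fw)) < 2) {
    stop("insufficient data: need >= 2 observations at distinct moisture contents")
  }
  if (any(mc_pct_fw <= 0 | mc_pct_fw >= 100)) {
    stop("moisture content must lie strictly between 0 and 100% fresh weight")
  }
  if (any(sigma_d <= 0)) stop("sigma must be positive")
  x <- log10(mc_pct_fw); y <- log10(sigma_d)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  K_E <- if (!is.null(temperature_C) && !is.null(C_H) && !is.null(C_Q)) {
    unname(co[1]) + C_H * temperature_C + C_Q * temperature_C^2
  } else NA_real_
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(C_W = -unname(co[2]), K_E_star = unname(co[1]), K_E = K_E,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       rss = rss, n = length(x))
}

#' Moisture content achieving a target longevity
#'
#' Inverts the viability equation for storage design: the moisture content
#' (% fresh weight) at which seeds held at `temperature_C` have longevity
#' `target_sigma`. [predict_sigma()] at the result reproduces the target.
#'
#' @param constants a [viability_constants()] object with `C_W != 0`.
#' @param temperature_C storage temperature, degC.
#' @param target_sigma desired sigma, days per probit (> 0).
#' @return moisture content in (0, 100) % fresh weight; an error if the
#'   required moisture is infeasible.
#' @export
solve_mc_for_sigma <- function(constants, temperature_C, target_sigma) {
  stopifnot(inherits(constants, "viability_constants"))
  if (constants$C_W == 0) stop("C_W = 0: sigma does not depend on moisture")
  if (any(target_sigma <= 0)) stop("target sigma must be positive")
  mc <- 10^((constants$K_E - constants$C_H * temperature_C -
               constants$C_Q * temperature_C^2 - log10(target_sigma)) /
              constants$C_W)
  if (any(mc <= 0 | mc >= 100)) {
    stop(sprintf("infeasible target: required MC = %g%% lies outside (0, 100)",
                 mc[which(mc <= 0 | mc >= 100)[1]]))
  }
  mc
}

#' Write viability-equation constants to JSON
#'
#' @param constants a [viability_constants()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_viability_constants <- function(constants, path) {
  stopifnot(inherits(constants, "viability_constants"))
  jsonlite::write_json(unclass(constants), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read viability-equation constants from JSON
#'
#' @param path file written by [write_viability_constants()].
#' @return a `viability_constants` object.
#' @export
read_viability_constants <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  viability_constants(x$K_E, x$C_W, x$C_H, x$C_Q)
}
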