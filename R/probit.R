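#' Probit transform of a germination percentage
#'
#' Converts a germination percentage to probit units. The package uses the
#' classical normal-equivalent-deviate-plus-5 (NED+5) convention throughout,
#' so 50% germination maps to exactly 5 probits and ordinary germination
#' percentages stay on a positive scale. The pure NED convention (50% -> 0)
#' is available via `ned = TRUE`.
#'
#' @param pct numeric vector of germination percentages, strictly between 0
#'   and 100. Exact 0% or 100% observations are outside the domain of the
#'   transform; they must be handled by a correction policy before
#'   transformation (see [fit_viability_line()]).
#' @param ned logical; if `TRUE`, return the normal equivalent deviate
#'   without the +5 offset.
#' @return numeric vector of viabilities in probit units.
#' @seealso [inverse_probit()]
#' @examples
#' probit(50)              # 5
#' probit(c(15.87, 84.13)) # about 4 and 6
#' @export
probit <- function(pct, ned = FALSE) {
  if (!is.numeric(pct)) stop("`pct` must be numeric")
  bad <- !is.na(pct) & (pct <= 0 | pct >= 100)
  if (any(bad)) {
    stop(
      "germination percentage must lie strictly between 0 and 100 ",
      "(got ", paste(format(pct[bad]), collapse = ", "), "). ",
      "0% and 100% observations must be handled by a correction policy: ",
      "see the `correction` argument of fit_viability_line(), or use the ",
      "count-based fit_viability_glm() which needs no correction."
    )
  }
  stats::qnorm(pct / 100) + if (isTRUE(ned)) 0 else 5
}

#' Inverse probit: viability in probit units to germination percentage
#'
#' @param v numeric vector of viabilities in probit units (NED+5 convention
#'   by default, so `inverse_probit(5)` is 50).
#' @param ned logical; if `TRUE`, `v` is interpreted as a plain normal
#'   equivalent deviate (no +5 offset).
#' @return germination percentage in (0, 100); strictly increasing in `v`.
#' @examples
#' inverse_probit(5)  # 50
#' inverse_probit(4)  # 15.866
#' @export
inverse_probit <- function(v, ned = FALSE) {
  if (!is.numeric(v)) stop("`v` must be numeric")
  100 * stats::pnorm(v - if (isTRUE(ned)) 0 else 5)
}
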