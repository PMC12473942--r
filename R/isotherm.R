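## Empirical water-sorption isotherms (equilibrium moisture content vs
## water activity a_w = RH/100) and moisture-basis bookkeeping.

#' Moisture content (% fresh weight) from fresh and dry masses
#'
#' Gravimetric moisture content from the oven-dry method (e.g. 103 degC for
#' 17 h): `100 * (fresh - dry) / fresh`.
#'
#' @param fresh_mg fresh (wet) mass.
#' @param dry_mg dry mass; must satisfy `0 < dry_mg <= fresh_mg`.
#' @return moisture content, % fresh-weight basis.
#' @examples
#' mc_fresh_from_weights(100, 90) # 10
#' @export
mc_fresh_from_weights <- function(fresh_mg, dry_mg) {
  if (any(dry_mg <= 0)) stop("dry mass must be positive")
  if (any(dry_mg > fresh_mg)) {
    stop("measurement-order error: dry mass exceeds fresh mass")
  }
  100 * (fresh_mg - dry_mg) / fresh_mg
}

#' Convert moisture content between fresh- and dry-weight bases
#'
#' Fresh basis expresses water as a percentage of total (fresh) mass; dry
#' basis as a percentage of dry mass (100 * g H2O / g DW). Conversions:
#' fresh -> dry `100*mc/(100-mc)`; dry -> fresh `100*mc/(100+mc)`. The two
#' round-trip to within 1e-12.
#'
#' @param mc moisture content(s), %.
#' @param from,to `"fresh"` or `"dry"`.
#' @return converted moisture content, %.
#' @examples
#' convert_mc_basis(17, from = "dry", to = "fresh") # 14.53
#' @export
convert_mc_basis <- function(mc, from = c("fresh", "dry"), to = c("fresh", "dry")) {
  from <- match.arg(from); to <- match.arg(to)
  if (any(mc < 0)) stop("moisture content cannot be negative")
  if (from == "fresh" && any(mc >= 100)) {
    stop("domain error: fresh-basis moisture content must be < 100%")
  }
  if (from == to) return(mc)
  if (from == "fresh") 100 * mc / (100 - mc) else 100 * mc / (100 + mc)
}

#' Build a water-sorption isotherm from replicate points
#'
#' Averages replicate equilibrium moisture contents at each water activity
#' and returns the curve sorted by `a_w`. Monotonicity violations (mean MC
#' decreasing as `a_w` increases) are flagged, never silently reordered —
#' on a sound isotherm equilibrium moisture rises with water activity.
#'
#' @param points data frame with columns `a_w` (0-1) and `mc_pct_fw`
#'   (0-100, exclusive); a `replicate` column is allowed and ignored for
#'   averaging; a `species` column, if present, must be constant.
#' @param species species label of the curve.
#' @param temperature_C equilibration temperature, degC.
#' @return object of class `isotherm_curve`: `species`, `temperature_C`,
#'   `points` (data frame `a_w`, `mc_pct_fw`, `n_reps`, ascending in
#'   `a_w`), `violations` (data frame of offending adjacent pairs).
#' @export
build_isotherm <- function(points, species = NA_character_,
                           temperature_C = NA_real_) {
  .check_columns(points, c("a_w", "mc_pct_fw"), "isotherm points")
  if (any(points$a_w < 0 | points$a_w > 1)) stop("a_w must lie in [0, 1]")
  if (any(points$mc_pct_fw <= 0 | points$mc_pct_fw >= 100)) {
    stop("mc_pct_fw must lie strictly between 0 and 100")
  }
  if ("species" %in% names(points)) {
    sp <- unique(points$species)
    if (length(sp) > 1) {
      stop("input error: points carry conflicting species labels: ",
           paste(sp, collapse = ", "))
    }
    if (is.na(species)) species <- sp
  }
  if (length(unique(points$a_w)) < 2) {
    stop("need >= 2 distinct water activities")
  }
  mc <- tapply(points$mc_pct_fw, points$a_w, mean)
  n <- tapply(points$mc_pct_fw, points$a_w, length)
  aw <- as.numeric(names(mc))
  ord <- order(aw)
  curve <- data.frame(a_w = aw[ord], mc_pct_fw = as.vector(mc)[ord],
                      n_reps = as.vector(n)[ord])
  d <- diff(curve$mc_pct_fw)
  viol <- which(d < 0)
  violations <- data.frame(a_w_lo = curve$a_w[viol], a_w_hi = curve$a_w[viol + 1],
                           mc_lo = curve$mc_pct_fw[viol],
                           mc_hi = curve$mc_pct_fw[viol + 1])
  structure(list(species = species, temperature_C = temperature_C,
                 points = curve, violations = violations),
            class = "isotherm_curve")
}

#' @export
print.isotherm_curve <- function(x, ...) {
  cat(sprintf("Water-sorption isotherm: %s at %g degC, %d points\n",
              x$species, x$temperature_C, nrow(x$points)))
  print(x$points, row.names = FALSE)
  if (nrow(x$violations)) {
    cat("warning:", nrow(x$violations), "monotonicity violation(s) flagged\n")
  }
  invisible(x)
}

#' Interpolate equilibrium moisture content at a relative humidity
#'
#' Piecewise-linear interpolation of the isotherm in water activity
#' (`a_w = rh_pct / 100`); exact at the measured points. Extrapolation
#' beyond the measured a_w range is refused.
#'
#' @param curve an [build_isotherm()] curve.
#' @param rh_pct relative humidity, %; `rh_pct/100` must lie within the
#'   curve's a_w range.
#' @return equilibrium moisture content, % fresh weight.
#' @export
interpolate_mc <- function(curve, rh_pct) {
  stopifnot(inherits(curve, "isotherm_curve"))
  aw <- rh_pct / 100
  rng <- range(curve$points$a_w)
  if (any(aw < rng[1] | aw > rng[2])) {
    stop(sprintf("extrapolation refused: rh = %g%% is outside the measured a_w range [%g, %g]",
                 rh_pct[which(aw < rng[1] | aw > rng[2])[1]], rng[1], rng[2]))
  }
  stats::approx(curve$points$a_w, curve$points$mc_pct_fw, xout = aw,
                ties = "ordered")$y
}

#' Load isotherm points from CSV
#'
#' Columns: `species`, `temperature_C`, `a_w`, `replicate`, `mc_pct_fw`.
#'
#' @param path CSV path.
#' @return data frame of isotherm points.
#' @export
load_isotherm_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .check_columns(df, c("a_w", "mc_pct_fw"), "isotherm CSV")
  df
}
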