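## Association of seed-lot P50 with collection-site climate covariates,
## per genus, by ordinary least squares / Pearson correlation.

#' Load a site-climate table from CSV
#'
#' Columns: `lot_id`, `annual_temp_C`, `annual_precip_mm`, `elevation_m`
#' (e.g. a WorldClim extract for each collection site).
#'
#' @param path CSV path.
#' @return validated data frame of climate records.
#' @export
load_climate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .check_columns(df, c("lot_id", "annual_temp_C", "annual_precip_mm",
                       "elevation_m"), "climate table")
  if (any(!is.na(df$annual_precip_mm) & df$annual_precip_mm < 0)) {
    stop("validation error: annual_precip_mm must be >= 0")
  }
  df
}

#' Join per-lot P50 estimates with climate covariates
#'
#' Inner join on `lot_id` of half-life estimates, site climate and lot
#' metadata (for the genus label). Lots present on one side only are
#' recorded in the `unmatched` attribute, never silently dropped without
#' trace.
#'
#' @param fits either a data frame with columns `lot_id`, `p50_d`, or a
#'   named list of `viability_fit` objects (names = lot ids).
#' @param climate data frame with `lot_id`, `annual_temp_C`,
#'   `annual_precip_mm`, `elevation_m`.
#' @param lots seed-lot metadata with `lot_id` and `genus` (see
#'   [load_seed_lots()]); optional — without it the joined table has no
#'   genus column.
#' @return data frame `lot_id`, `p50_d`, climate covariates (and `genus`),
#'   with attribute `unmatched` listing lot ids that failed to join.
#' @export
join_p50_climate <- function(fits, climate, lots = NULL) {
  if (is.list(fits) && !is.data.frame(fits)) {
    if (is.null(names(fits))) stop("a list of fits must be named by lot_id")
    fits <- data.frame(
      lot_id = names(fits),
      p50_d = vapply(fits, function(f) f$p50_d, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  .check_columns(fits, c("lot_id", "p50_d"), "fits")
  .check_columns(climate, c("lot_id", "annual_temp_C", "annual_precip_mm",
                            "elevation_m"), "climate table")
  joined <- merge(fits, climate, by = "lot_id")
  if (nrow(joined) == 0) {
    stop("join error: no lot_id overlap between fits and climate table")
  }
  if (!is.null(lots)) {
    .check_columns(lots, c("lot_id", "genus"), "seed-lot table")
    joined <- merge(joined, lots[, c("lot_id", "genus")], by = "lot_id",
                    all.x = TRUE)
  }
  unmatched <- c(setdiff(fits$lot_id, climate$lot_id),
                 setdiff(climate$lot_id, fits$lot_id))
  attr(joined, "unmatched") <- unmatched
  joined
}

#' Simple linear association of P50 with one covariate
#'
#' Ordinary least squares of `y` on `x` plus the Pearson correlation; the
#' reported `r_squared` is the square of the correlation (identical to the
#' regression R^2 for simple regression).
#'
#' @param x covariate values (n >= 3, not constant).
#' @param y response values (e.g. P50 in days).
#' @return list with `n`, `slope`, `intercept`, `r`, `r_squared`.
#' @examples
#' linear_r2(c(1, 2, 3), c(1, 2, 4)) # r_squared = 27/28
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0) stop("degenerate covariate: x is constant")
  co <- stats::coef(stats::lm(y ~ x))
  if (stats::sd(y) == 0) {
    warning("response has zero variance; r set to 0")
    r <- 0
  } else {
    r <- stats::cor(x, y)
  }
  list(n = length(x), slope = unname(co[2]), intercept = unname(co[1]),
       r = r, r_squared = r^2)
}

#' Per-genus climate-longevity associations
#'
#' [linear_r2()] of P50 on each covariate within each genus; genus groups
#' with fewer than 3 lots are skipped with a recorded reason. An optional
#' include-list restricts the lots entering the regressions (the published
#' analyses sometimes use a stated subset of the fitted lots).
#'
#' @param table joined table from [join_p50_climate()] (needs `genus`).
#' @param covariates covariate column names to test.
#' @param response response column (default `p50_d`).
#' @param log10_response if `TRUE`, regress `log10(response)` instead.
#' @param include optional character vector of `lot_id`s to keep.
#' @return data frame with one row per genus x covariate: `genus`,
#'   `covariate`, `n`, `slope`, `intercept`, `r`, `r_squared`; attribute
#'   `skipped` records genus/covariate pairs not analysed and why.
#' @export
genus_grouped_association <- function(table,
                                      covariates = c("annual_temp_C",
                                                     "annual_precip_mm",
                                                     "elevation_m"),
                                      response = "p50_d",
                                      log10_response = FALSE,
                                      include = NULL) {
  .check_columns(table, c("genus", response, covariates), "association table")
  if (!is.null(include)) table <- table[table$lot_id %in% include, ]
  out <- list(); skipped <- list()
  for (g in sort(unique(table$genus))) {
    sub <- table[table$genus == g, ]
    for (cv in covariates) {
      y <- sub[[response]]
      if (isTRUE(log10_response)) y <- log10(y)
      ok <- !(is.na(sub[[cv]]) | is.na(y))
      if (sum(ok) < 3) {
        skipped[[length(skipped) + 1]] <- data.frame(
          genus = g, covariate = cv,
          reason = sprintf("only %d complete lots (need >= 3)", sum(ok)))
        next
      }
      res <- linear_r2(sub[[cv]][ok], y[ok])
      out[[length(out) + 1]] <- data.frame(
        genus = g, covariate = cv, n = res$n, slope = res$slope,
        intercept = res$intercept, r = res$r, r_squared = res$r_squared)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(genus = character(0), covariate = character(0), n = integer(0),
               slope = numeric(0), intercept = numeric(0), r = numeric(0),
               r_squared = numeric(0))
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(genus = character(0), covariate = character(0),
               reason = character(0))
  res
}
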