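## Germination test tables: validated CSV I/O, replicate summaries, and
## one-way ANOVA with Student-Newman-Keuls pairwise comparisons.

.check_columns <- function(df, cols, what = "input") {
  if (!is.data.frame(df)) stop(what, " must be a data frame")
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("schema error: ", what, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Validate a table of germination records
#'
#' Checks the row-level invariants of a germination test table:
#' `0 <= n_germ <= n_sown`, `n_sown > 0`, `time_d >= 0`, `replicate >= 1`.
#'
#' @param records data frame with columns `lot_id`, `regime_id`, `time_d`,
#'   `replicate`, `n_sown`, `n_germ`.
#' @param rows optional original line numbers used in error messages
#'   (defaults to the row indices).
#' @return `records`, invisibly, if valid; otherwise an error naming every
#'   offending row and the rule it breaks.
#' @export
validate_germination <- function(records, rows = NULL) {
  .check_columns(records,
                 c("lot_id", "regime_id", "time_d", "replicate", "n_sown", "n_germ"),
                 "germination table")
  if (is.null(rows)) rows <- seq_len(nrow(records))
  problems <- character(0)
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) problems <<- c(problems, paste0("row ", rows[idx], ": ", msg))
  }
  bad(is.na(records$n_sown) | records$n_sown <= 0, "n_sown must be > 0")
  bad(!is.na(records$n_sown) & (is.na(records$n_germ) | records$n_germ < 0 |
                                  records$n_germ > records$n_sown),
      "n_germ must satisfy 0 <= n_germ <= n_sown")
  bad(is.na(records$time_d) | records$time_d < 0, "time_d must be >= 0")
  bad(is.na(records$replicate) | records$replicate < 1,
      "replicate must be a positive integer")
  if (length(problems)) {
    stop("validation error:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(records)
}

#' Load a germination test table from CSV
#'
#' Reads a comma-separated, UTF-8, headed CSV of replicate germination tests
#' (columns `lot_id`, `regime_id`, `time_d`, `replicate`, `n_sown`,
#' `n_germ`), validates every row against the record invariants, and
#' preserves row order. Malformed rows are reported with their file line
#' numbers (header = line 1).
#'
#' @param path path to the CSV file.
#' @return a validated data frame of germination records.
#' @export
load_germination_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_germination(df, rows = seq_len(nrow(df)) + 1L)
  df$time_d <- as.numeric(df$time_d) # days may be fractional
  df
}

#' Write a germination table to CSV
#'
#' Inverse of [load_germination_table()]; a written table loads back to
#' identical records.
#'
#' @param records validated germination data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_germination_table <- function(records, path) {
  validate_germination(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load seed-lot metadata from CSV
#'
#' Columns: `lot_id`, `species`, `genus` (Salix or Populus),
#' `collection_date` (ISO-8601; incomplete dates load as `NA`), `latitude`,
#' `longitude` (decimal degrees), `elevation_m`, and optionally `tsw_mg`
#' (thousand-seed weight, mg).
#'
#' @param path CSV path; defaults to the bundled table of the study's
#'   Salix and Populus collections.
#' @return data frame of seed lots with `collection_date` parsed to `Date`.
#' @export
load_seed_lots <- function(path = system.file("extdata", "seed_lots.csv",
                                              package = "seedspan")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .check_columns(df, c("lot_id", "species", "genus", "collection_date",
                       "latitude", "longitude", "elevation_m"), "seed-lot table")
  badg <- !df$genus %in% c("Salix", "Populus")
  if (any(badg)) {
    stop("validation error: genus must be 'Salix' or 'Populus' (rows ",
         paste(which(badg), collapse = ", "), ")")
  }
  if (any(!is.na(df$elevation_m) & df$elevation_m < 0)) {
    stop("validation error: elevation_m must be >= 0")
  }
  parsed <- as.Date(df$collection_date, format = "%Y-%m-%d")
  if (any(is.na(parsed) & !is.na(df$collection_date) & nzchar(df$collection_date))) {
    message("note: ", sum(is.na(parsed)), " collection date(s) incomplete; loaded as NA")
  }
  df$collection_date <- parsed
  df
}

#' Load storage-regime definitions from CSV
#'
#' Columns: `regime_id`, `temperature_C`, `rh_pct` (0-100, may be empty for
#' liquid-nitrogen storage), `mc_pct_fw` (optional), `label`.
#'
#' @param path CSV path.
#' @return validated data frame of regimes.
#' @export
load_storage_regimes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .check_columns(df, c("regime_id", "temperature_C"), "regime table")
  if ("rh_pct" %in% names(df)) {
    bad <- !is.na(df$rh_pct) & (df$rh_pct < 0 | df$rh_pct > 100)
    if (any(bad)) stop("validation error: rh_pct must lie in [0, 100] (rows ",
                       paste(which(bad), collapse = ", "), ")")
  }
  if ("mc_pct_fw" %in% names(df)) {
    bad <- !is.na(df$mc_pct_fw) & (df$mc_pct_fw <= 0 | df$mc_pct_fw >= 100)
    if (any(bad)) stop("validation error: mc_pct_fw must lie in (0, 100) (rows ",
                       paste(which(bad), collapse = ", "), ")")
  }
  df
}

#' Germination percentage of each record
#'
#' @param records germination data frame.
#' @return numeric vector `100 * n_germ / n_sown`.
#' @export
germination_pct <- function(records) {
  .check_columns(records, c("n_sown", "n_germ"))
  100 * records$n_germ / records$n_sown
}

#' Summarize germination tests by group
#'
#' Mean and standard error of the replicate germination percentages within
#' each group (default grouping: lot x regime x storage time), the way
#' "mean +/- SE of five replicates of 20 seeds" tables are built.
#'
#' @param records germination data frame.
#' @param group_by character vector of grouping columns.
#' @return data frame with the grouping columns plus `mean_pct`, `se_pct`
#'   (sample SD / sqrt(n); 0 for a single replicate is not defined and
#'   returns NA), and `n_reps`. Empty input yields an empty frame.
#' @export
summarize_germination <- function(records,
                                  group_by = c("lot_id", "regime_id", "time_d")) {
  .check_columns(records, c(group_by, "n_sown", "n_germ"))
  if (nrow(records) == 0) {
    out <- records[0, group_by, drop = FALSE]
    out$mean_pct <- numeric(0); out$se_pct <- numeric(0); out$n_reps <- integer(0)
    return(out)
  }
  pct <- germination_pct(records)
  key <- interaction(records[group_by], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    g <- records[i[1], group_by, drop = FALSE]
    x <- pct[i]
    g$mean_pct <- mean(x)
    g$se_pct <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    g$n_reps <- length(x)
    g
  }))
  rownames(out) <- NULL
  out
}

# Stepwise Student-Newman-Keuls on k ordered means. Returns a k x k logical
# matrix (in mean-descending order) of pairs declared significantly
# different. Non-significant stretches propagate: once a range test fails,
# every pair inside it is declared non-significant and never tested.
.snk_matrix <- function(means, n, mse, df, alpha) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; nn <- n[ord]
  sig <- matrix(FALSE, k, k)
  ns <- matrix(FALSE, k, k)
  for (r in k:2) {
    for (i in 1:(k - r + 1)) {
      j <- i + r - 1
      if (ns[i, j]) next
      n_h <- 2 / (1 / nn[i] + 1 / nn[j])
      crit <- stats::qtukey(1 - alpha, nmeans = r, df = df) * sqrt(mse / n_h)
      if ((m[i] - m[j]) >= crit) {
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        for (a in i:(j - 1)) for (b in (a + 1):j) ns[a, b] <- TRUE
      }
    }
  }
  list(sig = sig, order = ord)
}

# Compact letter display for an ordered significance matrix: maximal runs of
# mutually non-different means share a letter. With SNK's interval structure
# (a non-significant stretch covers all its sub-pairs) runs are intervals.
.snk_letters <- function(sig) {
  k <- nrow(sig)
  intervals <- list()
  i <- 1
  for (i in 1:k) {
    j <- i
    while (j < k && !sig[i, j + 1]) j <- j + 1
    intervals[[length(intervals) + 1]] <- c(i, j)
  }
  # keep maximal intervals only
  keep <- vapply(seq_along(intervals), function(a) {
    !any(vapply(seq_along(intervals), function(b) {
      b != a && intervals[[b]][1] <= intervals[[a]][1] &&
        intervals[[b]][2] >= intervals[[a]][2]
    }, logical(1)))
  }, logical(1))
  intervals <- intervals[keep]
  letters_out <- rep("", k)
  for (a in seq_along(intervals)) {
    rng <- intervals[[a]][1]:intervals[[a]][2]
    letters_out[rng] <- paste0(letters_out[rng], letters[a])
  }
  letters_out
}

#' Compare germination groups: one-way ANOVA + Student-Newman-Keuls
#'
#' One-way ANOVA on replicate germination percentages followed by the
#' stepwise Student-Newman-Keuls (SNK) procedure on studentized-range
#' quantiles, the standard workflow for germination tables with
#' significance letters. Percentages are analysed untransformed. When a
#' `control` group is named, each group also gets a significant/not flag for
#' its SNK comparison against the control.
#'
#' If every group has zero within-group variance the ANOVA is degenerate;
#' the function then warns and falls back to exact equality comparison
#' (groups flagged significant iff their means differ from the control's).
#'
#' @param pct numeric vector of replicate germination percentages.
#' @param group vector of group labels, same length as `pct`.
#' @param control optional label of the reference group.
#' @param alpha significance level for SNK (default 0.05).
#' @param diagnostics if `TRUE`, run Shapiro-Wilk normality (on residuals)
#'   and Levene homogeneity checks and warn (never gate) when either
#'   p < 0.05.
#' @return object of class `group_comparison`: `$anova` (F, df, p),
#'   `$groups` (group, mean_pct, n, letter, significant_vs_control),
#'   `$method`, `$alpha`, `$control`, `$zero_variance_fallback`.
#' @examples
#' fresh <- c(100, 100, 100, 100, 91.65)
#' dry <- c(0, 5, 5, 10, 15)
#' compare_groups(c(fresh, dry), rep(c("fresh", "dry"), each = 5),
#'                control = "fresh")
#' @export
compare_groups <- function(pct, group, control = NULL, alpha = 0.05,
                           diagnostics = FALSE) {
  if (length(pct) != length(group)) stop("`pct` and `group` lengths differ")
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  n_by <- tapply(pct, group, length)
  if (any(n_by < 2)) stop("every group needs >= 2 replicates")
  if (!is.null(control) && !control %in% levels(group)) {
    stop("control group '", control, "' not found")
  }

  gm <- tapply(pct, group, mean)
  lv <- levels(group)

  var_by <- tapply(pct, group, stats::var)
  if (all(var_by == 0)) {
    warning("all groups have zero within-group variance; ",
            "falling back to exact equality comparison")
    sigvc <- if (is.null(control)) rep(NA, length(lv)) else gm != gm[control]
    # equality-based letters: identical means share a letter
    u <- match(gm, sort(unique(gm), decreasing = TRUE))
    groups <- data.frame(group = lv, mean_pct = as.vector(gm),
                         n = as.vector(n_by), letter = letters[u],
                         significant_vs_control = as.vector(sigvc))
    return(structure(list(anova = c(F = NA, df1 = NA, df2 = NA, p = NA),
                          groups = groups, method = "exact-equality",
                          alpha = alpha, control = control,
                          zero_variance_fallback = TRUE),
                     class = "group_comparison"))
  }

  fit <- stats::aov(pct ~ group)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
  df1 <- tab[["Df"]][1]; df2 <- tab[["Df"]][2]
  mse <- tab[["Mean Sq"]][2]

  if (isTRUE(diagnostics)) {
    sw <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                   error = function(e) NA_real_)
    lev <- tryCatch(car::leveneTest(pct ~ group)[["Pr(>F)"]][1],
                    error = function(e) NA_real_)
    if (!is.na(sw) && sw < 0.05) {
      warning(sprintf("residual normality questionable (Shapiro-Wilk p = %.3g)", sw))
    }
    if (!is.na(lev) && lev < 0.05) {
      warning(sprintf("variance homogeneity questionable (Levene p = %.3g)", lev))
    }
  }

  snk <- .snk_matrix(as.vector(gm), as.vector(n_by), mse, df2, alpha)
  # map back from mean-descending order to level order
  sig_lv <- matrix(FALSE, length(lv), length(lv),
                   dimnames = list(lv, lv))
  sig_lv[snk$order, snk$order] <- snk$sig
  letter_lv <- character(length(lv))
  letter_lv[snk$order] <- .snk_letters(snk$sig)

  sigvc <- if (is.null(control)) rep(NA, length(lv)) else sig_lv[, control]

  groups <- data.frame(group = lv, mean_pct = as.vector(gm),
                       n = as.vector(n_by), letter = letter_lv,
                       significant_vs_control = as.vector(sigvc))
  structure(
    list(anova = c(F = Fv, df1 = df1, df2 = df2, p = p),
         groups = groups, pairwise_significant = sig_lv, method = "snk",
         alpha = alpha, control = control, zero_variance_fallback = FALSE),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$method == "exact-equality") {
    cat("Group comparison (degenerate: exact equality, zero variance)\n")
  } else {
    cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g; SNK at alpha = %g\n",
                x$anova["df1"], x$anova["df2"], x$anova["F"], x$anova["p"],
                x$alpha))
  }
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' The capsule-maturity germination table bundled with the package
#'
#' Mean +/- SE germination (five replicates of twenty seeds) of four
#' Salicaceae species at five capsule development stages, scored fresh and
#' after drying at 15 degC / 15% RH, with the published significance
#' letters. Transcribed from the printed source table.
#'
#' @return data frame with columns `species`, `genus`, `stage`,
#'   `water_status`, `mean_pct`, `se_pct`, `snk_letter`,
#'   `significant_decline`.
#' @export
maturity_table <- function() {
  utils::read.csv(system.file("extdata", "maturity_germination.csv",
                              package = "seedspan"),
                  stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Dry-room P50 estimates bundled with the package
#'
#' The published interpolated half-lives (days) of eight Salix and seven
#' Populus seed lots stored at 15 degC, 15% RH.
#'
#' @return data frame with columns `lot_id`, `species`, `genus`, `p50_d`.
#' @export
dry_room_p50_table <- function() {
  utils::read.csv(system.file("extdata", "dry_room_p50.csv",
                              package = "seedspan"),
                  stringsAsFactors = FALSE, encoding = "UTF-8")
}
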