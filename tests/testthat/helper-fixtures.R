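# Shared fixture builders. Everything is generated in code; no binary data.

# A noiseless germination series lying exactly on the probit line
# v = Ki - t/sigma, as percentages.
noiseless_series <- function(Ki, sigma_d, times) {
  list(time_d = times, germ_pct = inverse_probit(Ki - times / sigma_d))
}

# Replicate-level counts whose pooled proportions sit exactly on the line
# (fractional counts; used for estimator-agreement checks).
noiseless_records <- function(Ki, sigma_d, times, n_sown = 1e5) {
  p <- pnorm(Ki - times / sigma_d - 5)
  data.frame(lot_id = "x", regime_id = "r", time_d = times, replicate = 1L,
             n_sown = n_sown, n_germ = n_sown * p)
}

# Write a germination CSV and return its path.
write_germ_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "germ.csv")
  writeLines(c("lot_id,regime_id,time_d,replicate,n_sown,n_germ", lines), path)
  path
}
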