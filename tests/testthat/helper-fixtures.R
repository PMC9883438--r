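# Shared fixtures, all built in code.

# Headline parameter set of the extended model at the study's scale.
table1_params <- function(sigma = 50.65) {
  extended_params(a = 264.299, gamma0 = 0.999, gamma1 = -0.615, sigma = sigma)
}

# The default 26-year anomaly cycle used by the synthetic generator.
study_cycle <- function() {
  harmonic_cycle(period = 26, amplitude = 0.2, phase = 22.5, offset = 0)
}

# Exact power-law abundance data R = a * S^b (no noise).
powerlaw_abundance <- function(S, a, b, start_year = 1984) {
  tibble::tibble(year = start_year + seq_along(S) - 1, S = S, R = a * S^b)
}

# Abundance generated exactly from the extended model with sigma = 0:
# R_t = a * S_t^(gamma0 + gamma1 * T_t).
noisefree_extended <- function(params, S, T, start_year = 1984) {
  stopifnot(length(S) == length(T))
  tibble::tibble(
    year = start_year + seq_along(S) - 1,
    S = S,
    R = params$a * S^(params$gamma0 + params$gamma1 * T)
  )
}

# A minimal fitted-model stand-in carrying given residuals, for exercising
# diagnostics() in isolation.
fake_fit_with_residuals <- function(resids) {
  structure(list(residuals = resids), class = "extended_cushing_fit")
}

write_tmp_csv <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}
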