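# Shared fixture builders: all synthetic, generated in code.

make_obs_df <- function(n = 3) {
  data.frame(
    country_code = c("AAA", "BBB", "CCC")[seq_len(n)],
    ref_year = c(2000.5, 2010, 1995)[seq_len(n)],
    age_group = c("0-4", "5-14", "15-24")[seq_len(n)],
    source_type = c("VR", "SBH", "CENSUS")[seq_len(n)],
    series_id = paste0("s", seq_len(n)),
    sex_ratio_obs = c(1.10, 1.25, 0.95)[seq_len(n)],
    log_se_sampling = c(0.05, 0.10, 0.08)[seq_len(n)],
    deaths_male = NA_real_,
    deaths_female = NA_real_,
    stringsAsFactors = FALSE)
}

tiny_sim <- function(seed = 5, n_countries = 8, years = 2000:2011, ...) {
  sim_config(n_countries = n_countries, years = years, seed = seed, ...)
}

# Dense multivariate-Normal log density: independent oracle for the
# stationary AR(1) multiplier density (covariance tau^2 * rho^|i-j|).
dense_ar1_logdensity <- function(delta, rho, tau) {
  n <- length(delta)
  S <- tau^2 * rho^abs(outer(seq_len(n), seq_len(n), "-"))
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       drop(delta %*% solve(S, delta))))
}
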