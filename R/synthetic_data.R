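## Synthetic study inputs with known ground truth: declining total-mortality
## trajectories, a true sex-ratio-vs-mortality curve, AR(1) country
## multipliers, and noisy multi-source observations.

#' Default true global curve used in simulations
#'
#' A realistic expected-sex-ratio curve for mortality in childhood and
#' youth: the male:female ratio rises as total mortality declines, with
#' a mild reversal at very low mortality.
#'
#' @param age_group Age group label attached to the curve.
#' @return A [global_curve()].
#' @export
default_truth_curve <- function(age_group = "0-4") {
  global_curve(age_group,
               knots_logq = c(-7.5, -5.5, -4.0, -2.5, -1.2),
               values_logs = log(c(1.15, 1.19, 1.14, 1.07, 1.02)))
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: country count, year range,
#' the true curve, the AR(1) multiplier process (`rho_truth`,
#' `tau_truth`), source-specific non-sampling SDs, the source-type mix,
#' source-specific sampling-SE ranges (vital registration is nearly
#' complete, survey histories are noisier), the expected observation
#' count per country-year, total-mortality trajectory ranges, and the
#' exposure scale used to convert rates into death counts.
#'
#' @param n_countries Number of synthetic countries.
#' @param years Integer estimation years.
#' @param age_groups Reporting age groups to simulate.
#' @param curve_truth True [global_curve()] (recycled across age groups
#'   unless a named list is given).
#' @param rho_truth True AR(1) lag-1 correlation, in (0, 1).
#' @param tau_truth True stationary SD of log multipliers, `>= 0`.
#' @param sigma_by_source True non-sampling SDs per source type.
#' @param source_mix Sampling probabilities over source types (sums to 1).
#' @param sampling_se_range Named list of `c(lo, hi)` log-SE ranges per
#'   source type.
#' @param obs_per_country_year Expected observations per country-year
#'   (Poisson counts).
#' @param q0_range Range of the starting total-mortality probability.
#' @param decline_range Range of annual exponential decline rates.
#' @param totals_noise_sd SD of year-on-year log noise in the totals.
#' @param n_totals_draws Number of uncertainty draws around the totals
#'   (0 = totals treated as known).
#' @param totals_draw_sd Log-scale SD of the totals uncertainty draws.
#' @param srb Sex ratio at birth (male births per female birth).
#' @param cohort_range Range of the per-country cohort size (person-years
#'   entering an age group), used for death counts.
#' @param seed Integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_countries = 60,
                       years = 1990:2021,
                       age_groups = "0-4",
                       curve_truth = default_truth_curve(),
                       rho_truth = 0.9,
                       tau_truth = 0.1,
                       sigma_by_source = c(VR = 0.025, FBH = 0.05,
                                           SBH = 0.075, CENSUS = 0.05),
                       source_mix = c(VR = 0.5, FBH = 0.2, SBH = 0.2,
                                      CENSUS = 0.1),
                       sampling_se_range = list(VR = c(0.01, 0.05),
                                                FBH = c(0.05, 0.15),
                                                SBH = c(0.05, 0.15),
                                                CENSUS = c(0.02, 0.10)),
                       obs_per_country_year = 1,
                       q0_range = c(0.02, 0.25),
                       decline_range = c(0.01, 0.05),
                       totals_noise_sd = 0.02,
                       n_totals_draws = 0,
                       totals_draw_sd = 0.03,
                       srb = 1.05,
                       cohort_range = c(5e4, 5e5),
                       seed = 1) {
  if (abs(sum(source_mix) - 1) > 1e-12)
    stop_sexmort("source_mix must sum to 1")
  if (!all(names(source_mix) %in% SOURCE_TYPES))
    stop_sexmort("source_mix names must be source types")
  if (!is.finite(rho_truth) || rho_truth <= 0 || rho_truth >= 1)
    stop_sexmort("rho_truth must lie in (0, 1)")
  if (tau_truth < 0) stop_sexmort("tau_truth must be >= 0")
  if (any(sigma_by_source < 0)) stop_sexmort("all sigma must be >= 0")
  if (!all(age_groups %in% REPORTING_GROUPS))
    stop_sexmort("age_groups must be reporting groups")
  if (inherits(curve_truth, "global_curve"))
    curve_truth <- setNames(
      lapply(age_groups, function(a) {
        cv <- curve_truth; cv$age_group <- a; cv
      }), age_groups)
  structure(list(n_countries = as.integer(n_countries),
                 years = sort(as.integer(years)),
                 age_groups = age_groups,
                 curve_truth = curve_truth,
                 rho_truth = rho_truth, tau_truth = tau_truth,
                 sigma_by_source = sigma_by_source,
                 source_mix = source_mix,
                 sampling_se_range = sampling_se_range,
                 obs_per_country_year = obs_per_country_year,
                 q0_range = q0_range, decline_range = decline_range,
                 totals_noise_sd = totals_noise_sd,
                 n_totals_draws = as.integer(n_totals_draws),
                 totals_draw_sd = totals_draw_sd,
                 srb = srb, cohort_range = cohort_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_country_codes <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate total (both-sex) mortality trajectories
#'
#' Per country and age group, the probability of dying follows an
#' exponential decline `q(t) = q0 * exp(-r (t - t0) + e_t)` with
#' per-country starting level `q0` and decline rate `r` drawn from the
#' configured ranges and iid Normal log noise `e_t`; values are clipped
#' to (1e-6, 0.9).  Optionally attaches uncertainty draws around each
#' trajectory (log-Normal, `totals_draw_sd`).
#'
#' @param config A [sim_config()].
#' @return Data frame `country_code, year, age_group, q_total` (class
#'   `total_mortality`), with a `"draws"` attribute (long data frame
#'   with a `draw` column) when `n_totals_draws > 0`, plus per-country
#'   cohort sizes in attribute `"cohort"`.
#' @export
simulate_total_mortality <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  years <- config$years
  if (length(years) == 0) stop_sexmort("empty year range")
  set.seed(config$seed)
  codes <- sim_country_codes(config$n_countries)
  out <- list()
  for (ag in config$age_groups) {
    q0 <- exp(runif(config$n_countries, log(config$q0_range[1]),
                    log(config$q0_range[2])))
    r <- runif(config$n_countries, config$decline_range[1],
               config$decline_range[2])
    tt <- outer(rep(1, config$n_countries), years - years[1])
    noise <- matrix(rnorm(config$n_countries * length(years), 0,
                          config$totals_noise_sd),
                    config$n_countries)
    q <- pmin(pmax(q0 * exp(-r * tt + noise), 1e-6), 0.9)
    out[[ag]] <- data.frame(
      country_code = rep(codes, times = length(years)),
      year = rep(years, each = config$n_countries),
      age_group = ag,
      q_total = as.vector(q),
      stringsAsFactors = FALSE)
  }
  totals <- do.call(rbind, out)
  rownames(totals) <- NULL
  draws <- NULL
  if (config$n_totals_draws > 0) {
    draws <- do.call(rbind, lapply(seq_len(config$n_totals_draws), function(d) {
      z <- totals
      z$draw <- d
      z$q_total <- pmin(pmax(
        z$q_total * exp(rnorm(nrow(z), 0, config$totals_draw_sd)), 1e-6), 0.9)
      z
    }))
  }
  cohort <- exp(runif(config$n_countries, log(config$cohort_range[1]),
                      log(config$cohort_range[2])))
  structure(totals, class = c("total_mortality", "data.frame"),
            draws = draws, cohort = setNames(cohort, codes))
}

#' Simulate the true sex-ratio surface
#'
#' Draws stationary AR(1) log multipliers `delta` (mean 0, SD
#' `tau_truth`, lag-1 correlation `rho_truth`) per country and age
#' group, and sets the true sex ratio to
#' `S = f_truth(q_total) * exp(delta)` element-wise.
#'
#' @param totals Output of [simulate_total_mortality()].
#' @param config The same [sim_config()].
#' @return An object of class `synthetic_truth`: list with `totals`,
#'   `s_true` (data frame with column `s_true`), `delta` (list of
#'   country-by-year matrices per age group), and `config`.
#' @export
simulate_truth <- function(totals, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tau_truth < 0) stop_sexmort("tau_truth must be >= 0")
  years <- config$years
  codes <- sim_country_codes(config$n_countries)
  set.seed(config$seed + 1L)
  delta_list <- list()
  s_rows <- list()
  for (ag in config$age_groups) {
    Tn <- length(years)
    D <- matrix(0, config$n_countries, Tn,
                dimnames = list(codes, years))
    if (config$tau_truth > 0) {
      D[, 1] <- rnorm(config$n_countries, 0, config$tau_truth)
      if (Tn > 1) {
        sd_c <- config$tau_truth * sqrt(1 - config$rho_truth^2)
        for (t in 2:Tn)
          D[, t] <- config$rho_truth * D[, t - 1] +
            rnorm(config$n_countries, 0, sd_c)
      }
    }
    delta_list[[ag]] <- D
    tt <- totals[totals$age_group == ag, ]
    f <- expected_sex_ratio(tt$q_total, config$curve_truth[[ag]])
    d <- D[cbind(match(tt$country_code, codes), match(tt$year, years))]
    tt$s_true <- f * exp(d)
    s_rows[[ag]] <- tt
  }
  s_true <- do.call(rbind, s_rows)
  rownames(s_true) <- NULL
  structure(list(totals = totals, s_true = s_true, delta = delta_list,
                 config = config),
            class = "synthetic_truth")
}

#' Simulate noisy multi-source observations
#'
#' For each country-year-age cell, draws a Poisson number of
#' observations; each gets a source type from `source_mix`, a sampling
#' SE from the source's configured range (recorded in
#' `log_se_sampling`), and an observed log ratio equal to the true log
#' ratio plus independent sampling noise and source-specific
#' non-sampling noise.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The same [sim_config()].
#' @return A validated `obs_table`.
#' @export
simulate_observations <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (abs(sum(config$source_mix) - 1) > 1e-12)
    stop_sexmort("source_mix must sum to 1")
  set.seed(config$seed + 2L)
  cells <- truth$s_true
  n_obs <- rpois(nrow(cells), config$obs_per_country_year)
  idx <- rep(seq_len(nrow(cells)), n_obs)
  if (length(idx) == 0) stop_sexmort("no observations generated; raise obs_per_country_year")
  src <- sample(names(config$source_mix), length(idx), replace = TRUE,
                prob = config$source_mix)
  se_lo <- vapply(config$sampling_se_range[src], `[`, numeric(1), 1)
  se_hi <- vapply(config$sampling_se_range[src], `[`, numeric(1), 2)
  log_se <- runif(length(idx), se_lo, se_hi)
  sig <- config$sigma_by_source[src]
  e <- rnorm(length(idx), 0, log_se) + rnorm(length(idx), 0, sig)
  df <- data.frame(
    country_code = cells$country_code[idx],
    ref_year = cells$year[idx],
    age_group = cells$age_group[idx],
    source_type = src,
    series_id = paste0(src, "-", seq_along(idx)),
    sex_ratio_obs = cells$s_true[idx] * exp(e),
    log_se_sampling = log_se,
    deaths_male = NA_real_, deaths_female = NA_real_,
    stringsAsFactors = FALSE)
  as_obs_table(df, provenance = "synthetic")
}

#' Write all synthetic inputs and a manifest
#'
#' Writes the observation CSV, the totals CSV (plus a draws CSV when
#' uncertainty draws were simulated), the true sex-ratio surface, a
#' round-robin synthetic region map, per-country cohort sizes, and a
#' JSON manifest recording the seed and all truth parameters.
#'
#' @param truth A [simulate_truth()] result.
#' @param obs The matching `obs_table`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(truth, obs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- truth$config
  paths <- list(
    observations = file.path(dir, "observations.csv"),
    totals = file.path(dir, "totals.csv"),
    truth = file.path(dir, "truth_sex_ratio.csv"),
    regions = file.path(dir, "regions.csv"),
    cohort = file.path(dir, "cohort.csv"),
    manifest = file.path(dir, "simulation_manifest.json"))
  write_observations(obs, paths$observations)
  write.csv(as.data.frame(truth$totals), paths$totals, row.names = FALSE)
  write.csv(truth$s_true, paths$truth, row.names = FALSE)
  codes <- sim_country_codes(cfg$n_countries)
  regions <- data.frame(country_code = codes,
                        region = paste("Region",
                                       LETTERS[(seq_along(codes) - 1) %% 4 + 1]),
                        stringsAsFactors = FALSE)
  write.csv(regions, paths$regions, row.names = FALSE)
  cohort <- attr(truth$totals, "cohort")
  write.csv(data.frame(country_code = names(cohort), cohort = cohort,
                       row.names = NULL),
            paths$cohort, row.names = FALSE)
  draws <- attr(truth$totals, "draws")
  if (!is.null(draws)) {
    paths$totals_draws <- file.path(dir, "totals_draws.csv")
    write.csv(draws, paths$totals_draws, row.names = FALSE)
  }
  manifest <- list(seed = cfg$seed, n_countries = cfg$n_countries,
                   years = range(cfg$years), age_groups = cfg$age_groups,
                   rho_truth = cfg$rho_truth, tau_truth = cfg$tau_truth,
                   sigma_by_source = as.list(cfg$sigma_by_source),
                   source_mix = as.list(cfg$source_mix),
                   obs_per_country_year = cfg$obs_per_country_year,
                   curve_truth = lapply(cfg$curve_truth, function(cv)
                     list(knots_logq = cv$knots_logq,
                          values_logs = cv$values_logs)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
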