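## Probabilistic model: global expected-sex-ratio curve, AR(1) country
## multipliers, source-specific observation error model, priors, and the
## unnormalised joint posterior density.

#' Global expected-sex-ratio curve
#'
#' The expected sex ratio of mortality as a function of the total
#' (both-sex) probability of dying: piecewise linear in
#' (log q, log ratio) on a strictly increasing knot grid, flat beyond
#' the end knots.  This is the "no country deviation" benchmark; the
#' flexible form allows the rise of the ratio as mortality declines and
#' its reversal at very low mortality.
#'
#' @param age_group Reporting age group the curve applies to.
#' @param knots_logq Strictly increasing knot locations on natural-log
#'   total mortality.
#' @param values_logs Log expected sex ratio at each knot.
#' @return An object of class `global_curve`.
#' @export
global_curve <- function(age_group, knots_logq, values_logs) {
  if (length(knots_logq) < 2) stop_sexmort("a curve needs at least 2 knots")
  if (any(diff(knots_logq) <= 0))
    stop_sexmort("knots_logq must be strictly increasing")
  if (length(values_logs) != length(knots_logq))
    stop_sexmort("values_logs must match knots_logq in length")
  if (any(!is.finite(knots_logq)) || any(!is.finite(values_logs)))
    stop_sexmort("knots and values must be finite")
  structure(list(age_group = age_group,
                 knots_logq = as.numeric(knots_logq),
                 values_logs = as.numeric(values_logs)),
            class = "global_curve")
}

#' Expected sex ratio at a total mortality level
#'
#' Evaluates the global curve: linear interpolation of the log ratio at
#' `log(q_total)`, flat extrapolation outside the knot range, then
#' exponentiated.  Continuous in `q_total`.
#'
#' @param q_total Total (both-sex) probability of dying, in (0, 1);
#'   vectorised.
#' @param curve A [global_curve()].
#' @return Expected male:female mortality ratio(s).
#' @export
expected_sex_ratio <- function(q_total, curve) {
  stopifnot(inherits(curve, "global_curve"))
  if (any(!is.finite(q_total)) || any(q_total <= 0) || any(q_total >= 1))
    stop_sexmort("q_total must lie strictly in (0, 1)")
  exp(interp_flat(curve$knots_logq, curve$values_logs, log(q_total)))
}

# Piecewise-linear interpolation with flat extrapolation beyond end knots.
interp_flat <- function(knots, values, x) {
  approx(knots, values, xout = pmin(pmax(x, knots[1]), knots[length(knots)]),
         method = "linear", rule = 2)$y
}

# Interpolation weight matrix: rows sum to 1, two nonzeros per row
# (one at the boundary).  Used for Gaussian conditional updates of the
# knot values, and must agree exactly with interp_flat.
interp_weights <- function(knots, x) {
  K <- length(knots)
  x <- pmin(pmax(x, knots[1]), knots[K])
  k <- findInterval(x, knots, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), K - 1L)
  lam <- (x - knots[k]) / (knots[k + 1] - knots[k])
  A <- matrix(0, length(x), K)
  A[cbind(seq_along(x), k)] <- 1 - lam
  A[cbind(seq_along(x), k + 1L)] <- A[cbind(seq_along(x), k + 1L)] + lam
  A
}

#' Country multiplier series
#'
#' Log multipliers `delta` for one (country, age group): the multiplier
#' `P = exp(delta)` scales the expected sex ratio and fluctuates around
#' one.  The process is a stationary AR(1) on the log scale with lag-1
#' correlation `rho` and stationary SD `tau`.
#'
#' @param country_code 3-character country code.
#' @param age_group Reporting age group.
#' @param delta Numeric vector of log multipliers, one per model year.
#' @param rho Lag-1 correlation, in (0, 1).
#' @param tau Stationary SD, `>= 0`.
#' @return An object of class `multiplier_series`.
#' @export
multiplier_series <- function(country_code, age_group, delta, rho, tau) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1)
    stop_sexmort("rho must lie strictly in (0, 1)")
  if (!is.finite(tau) || tau < 0) stop_sexmort("tau must be >= 0")
  if (length(delta) < 1 || any(!is.finite(delta)))
    stop_sexmort("delta must be a nonempty finite vector")
  structure(list(country_code = country_code, age_group = age_group,
                 delta = as.numeric(delta), rho = rho, tau = tau),
            class = "multiplier_series")
}

#' Log density of a multiplier series
#'
#' Stationary AR(1) log density: `delta[1] ~ N(0, tau^2)` and
#' `delta[t] | delta[t-1] ~ N(rho * delta[t-1], tau^2 (1 - rho^2))`.
#' With `tau = 0` the process is a point mass at zero: returns `-Inf`
#' for any nonzero `delta` and `Inf` (degenerate) otherwise.
#'
#' @param series A [multiplier_series()].
#' @return Log density (scalar).
#' @export
multiplier_logdensity <- function(series) {
  stopifnot(inherits(series, "multiplier_series"))
  ar1_logdensity(matrix(series$delta, nrow = 1), series$rho, series$tau)
}

# Vectorised over countries: D is a C x T matrix of log multipliers.
ar1_logdensity <- function(D, rho, tau) {
  if (tau == 0) return(if (all(D == 0)) Inf else -Inf)
  Tn <- ncol(D)
  ll <- sum(dnorm(D[, 1], 0, tau, log = TRUE))
  if (Tn > 1) {
    sd_c <- tau * sqrt(1 - rho^2)
    ll <- ll + sum(dnorm(D[, -1, drop = FALSE],
                         rho * D[, -Tn, drop = FALSE], sd_c, log = TRUE))
  }
  ll
}

# Tridiagonal precision matrix of the stationary AR(1) (marginal
# variance tau^2, lag-1 correlation rho).
ar1_precision <- function(Tn, rho, tau) {
  if (tau <= 0) stop_sexmort("tau must be > 0 for a proper precision")
  s2 <- tau^2 * (1 - rho^2)
  Q <- diag(c(1, rep(1 + rho^2, max(Tn - 2, 0)), 1)[seq_len(Tn)] / s2,
            nrow = Tn)
  if (Tn > 1) {
    off <- -rho / s2
    Q[cbind(seq_len(Tn - 1), seq_len(Tn - 1) + 1)] <- off
    Q[cbind(seq_len(Tn - 1) + 1, seq_len(Tn - 1))] <- off
  }
  if (Tn == 1) Q[1, 1] <- 1 / tau^2
  Q
}

#' Source-specific non-sampling error model
#'
#' Non-sampling SD on the log-ratio scale per source type, capturing
#' systematic recall/misreporting/coverage error that differs between
#' vital registration, survey birth and sibling histories, and
#' censuses.
#'
#' @param sigma_by_source Named nonnegative numeric vector, names from
#'   `VR`, `FBH`, `SBH`, `CENSUS`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sigma_by_source) {
  if (is.null(names(sigma_by_source)) ||
      !all(names(sigma_by_source) %in% SOURCE_TYPES))
    stop_sexmort("sigma_by_source must be named with source types")
  if (any(!is.finite(sigma_by_source)) || any(sigma_by_source < 0))
    stop_sexmort("all sigma must be finite and >= 0")
  structure(list(sigma_by_source = sigma_by_source), class = "error_model")
}

#' Observation log likelihood
#'
#' Normal log density of the observed log sex ratio around the model
#' log ratio, with total variance equal to the observation's sampling
#' variance plus the squared non-sampling SD of its source type.  Weakly
#' informative observations (large total variance) contribute flat
#' likelihood terms, so the posterior pools towards informative ones.
#'
#' @param record One observation (a list or one-row `obs_table` with
#'   `sex_ratio_obs`, `log_se_sampling`, `source_type`).
#' @param s_model Model sex ratio (positive).
#' @param error_model An [error_model()].
#' @return Log likelihood (scalar, vectorised over rows of `record`).
#' @export
observation_loglik <- function(record, s_model, error_model) {
  stopifnot(inherits(error_model, "error_model"))
  sig <- error_model$sigma_by_source[record$source_type]
  if (any(is.na(sig))) stop_sexmort("source type missing from error model")
  if (any(!is.finite(s_model)) || any(s_model <= 0))
    stop_sexmort("s_model must be positive")
  v_tot <- record$log_se_sampling^2 + sig^2
  if (any(v_tot <= 0))
    stop_sexmort("total observation variance must be positive")
  sum(dnorm(log(record$sex_ratio_obs), log(s_model), sqrt(v_tot), log = TRUE))
}

#' Model configuration
#'
#' Collects knot placement, prior hyperparameters, the estimation year
#' grid, and sampler settings.  Priors: half-Normal(0, `tau_prior_scale`)
#' on the multiplier SD `tau` and each non-sampling SD `sigma_j`;
#' Uniform(0, 1) on the AR(1) correlation `rho`; on the curve knot
#' values, Normal(0, `first_knot_sd`) on the first knot, weak
#' Normal(0, `curve_value_sd`) on the others, and a second-difference
#' (random-walk-2 style) smoothness penalty with SD `curve_smooth_sd`.
#'
#' @param years Integer vector of estimation years.
#' @param n_knots Number of curve knots when `knots_logq` is `NULL`
#'   (placed at equally spaced quantiles of the observed log-mortality
#'   values, spanning the observed range).
#' @param knots_logq Optional explicit knot grid on log total mortality.
#' @param curve_smooth_sd SD of the second-difference smoothness prior.
#' @param first_knot_sd,curve_value_sd SDs of the Normal priors on the
#'   first and the remaining knot values.
#' @param tau_prior_scale,sigma_prior_scale Half-Normal scales for `tau`
#'   and the `sigma_j`.
#' @param n_draws Posterior draws kept (>= 500 for production use).
#' @param n_warmup Warmup (adaptation) iterations discarded.
#' @param thin Keep every `thin`-th post-warmup scan.
#' @param seed Integer seed for the sampler.
#' @param fixed Optional list fixing components for reduced/oracle runs:
#'   any of `curve` (a [global_curve()] or list by age group), `rho`,
#'   `tau`, `sigma` (named vector by source type).
#' @return An object of class `model_config`.
#' @export
model_config <- function(years = 1990:2021,
                         n_knots = 6,
                         knots_logq = NULL,
                         curve_smooth_sd = 0.1,
                         first_knot_sd = 1,
                         curve_value_sd = 5,
                         tau_prior_scale = 0.5,
                         sigma_prior_scale = 0.5,
                         n_draws = 1000,
                         n_warmup = 750,
                         thin = 1,
                         seed = 1,
                         fixed = list()) {
  stopifnot(curve_smooth_sd > 0, first_knot_sd > 0, curve_value_sd > 0,
            tau_prior_scale > 0, sigma_prior_scale > 0,
            n_draws >= 2, n_warmup >= 0, n_knots >= 2, thin >= 1)
  years <- sort(as.integer(years))
  structure(list(years = years, n_knots = n_knots, knots_logq = knots_logq,
                 curve_smooth_sd = curve_smooth_sd,
                 first_knot_sd = first_knot_sd,
                 curve_value_sd = curve_value_sd,
                 tau_prior_scale = tau_prior_scale,
                 sigma_prior_scale = sigma_prior_scale,
                 n_draws = as.integer(n_draws),
                 n_warmup = as.integer(n_warmup),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 fixed = fixed),
            class = "model_config")
}

# Log prior of curve knot values under a model_config.
curve_log_prior <- function(values, config) {
  ll <- dnorm(values[1], 0, config$first_knot_sd, log = TRUE)
  if (length(values) > 1)
    ll <- ll + sum(dnorm(values[-1], 0, config$curve_value_sd, log = TRUE))
  if (length(values) > 2)
    ll <- ll + sum(dnorm(diff(diff(values)), 0, config$curve_smooth_sd,
                         log = TRUE))
  ll
}

# Prior precision and (zero) mean matching curve_log_prior.
curve_prior_precision <- function(K, config) {
  P <- diag(c(1 / config$first_knot_sd^2,
              rep(1 / config$curve_value_sd^2, K - 1)), nrow = K)
  if (K > 2) {
    D2 <- diff(diag(K), differences = 2)
    P <- P + crossprod(D2) / config$curve_smooth_sd^2
  }
  P
}

half_normal_logdens <- function(x, scale) {
  if (x < 0) return(-Inf)
  dnorm(x, 0, scale, log = TRUE) + log(2)
}

#' Unnormalised log posterior density
#'
#' The joint density the sampler targets: the sum of all observation
#' log likelihoods, all country-multiplier AR(1) log densities, the
#' curve smoothness prior, and the hyperpriors on `tau`, `rho`, and the
#' non-sampling SDs.  Exposed for oracle testing (component-sum and
#' additivity checks) and diagnostics.
#'
#' @param params List with components `curves` (named list of
#'   [global_curve()] by age group), `delta` (named list of
#'   country-by-year matrices of log multipliers, rows named by country
#'   code), `hyper` (named list per age group with `rho`, `tau`), and
#'   `error_model` (an [error_model()]).
#' @param data An `obs_table` (may be empty for a prior-only value).
#' @param totals Data frame `country_code, year, age_group, q_total`
#'   covering every observation's cell.
#' @param config A [model_config()].
#' @return Unnormalised log posterior density (scalar).
#' @export
log_posterior <- function(params, data, totals, config) {
  stopifnot(inherits(config, "model_config"))
  years <- config$years
  lp <- 0
  for (ag in names(params$delta)) {
    D <- params$delta[[ag]]
    hyper <- params$hyper[[ag]]
    lp <- lp + ar1_logdensity(D, hyper$rho, hyper$tau)
    lp <- lp + curve_log_prior(params$curves[[ag]]$values_logs, config)
    lp <- lp + half_normal_logdens(hyper$tau, config$tau_prior_scale)
    lp <- lp + dunif(hyper$rho, 0, 1, log = TRUE)
  }
  for (s in params$error_model$sigma_by_source)
    lp <- lp + half_normal_logdens(s, config$sigma_prior_scale)
  if (nrow(data) > 0) {
    for (i in seq_len(nrow(data))) {
      rec <- as.list(data[i, ])
      ag <- rec$age_group
      D <- params$delta[[ag]]
      if (is.null(D)) stop_sexmort("no parameters for age group ", ag)
      t_idx <- nearest_year_index(rec$ref_year, years)
      q <- totals$q_total[totals$country_code == rec$country_code &
                            totals$year == years[t_idx] &
                            totals$age_group == ag]
      if (length(q) != 1)
        stop_sexmort("totals do not cover observation cell ",
                     rec$country_code, "/", years[t_idx], "/", ag)
      s_model <- expected_sex_ratio(q, params$curves[[ag]]) *
        exp(D[rec$country_code, t_idx])
      lp <- lp + observation_loglik(rec, s_model, params$error_model)
    }
  }
  lp
}

# An observation informs the model year nearest its (decimal) reference
# year; ties break to the earlier year, ends are clamped.
nearest_year_index <- function(ref_year, years) {
  vapply(ref_year, function(y) which.min(abs(years - y)), integer(1))
}
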