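## Posterior sampling for the hierarchical sex-ratio model, posterior
## trajectories of sex ratios and sex-specific mortality, and 90% interval
## summaries.
##
## Sampler: blocked Gibbs targeting log_posterior().  Country multiplier
## vectors have Gaussian full conditionals (tridiagonal AR(1) precision plus
## diagonal data precision); curve knot values have a Gaussian full
## conditional; tau (with an ancillarity-sufficiency interweaving step), rho,
## and the sigma_j use adaptive random-walk Metropolis on transformed scales.

#' Fit the hierarchical sex-ratio model
#'
#' Draws from the posterior of the global curve, the country
#' multipliers, and the hyperparameters (`tau`, `rho`, non-sampling SDs
#' by source), given a multi-source observation table and the total
#' (both-sex) mortality surface.  Age groups are fitted independently.
#' Countries without observations receive curve-driven estimates with
#' prior-width multiplier uncertainty.  Split-chain convergence
#' statistics for the hyperparameters are reported in
#' `$diagnostics`; values above 1.05 set a `"warn"` status rather than
#' failing silently.
#'
#' @param data An `obs_table`, nonempty for every modelled age group.
#' @param totals Data frame `country_code, year, age_group, q_total`
#'   covering the full country-year grid of every modelled age group.
#' @param config A [model_config()].
#' @return An object of class `posterior_trajectories`: per age group,
#'   draws of the sex ratio `S` (array `draw x country x year`), curve
#'   knot draws, hyperparameter draws, and the mortality grid.
#' @export
fit_model <- function(data, totals, config) {
  stopifnot(inherits(data, "obs_table"), inherits(config, "model_config"))
  age_groups <- sort(unique(data$age_group))
  if (length(age_groups) == 0) stop_sexmort("observation table is empty")
  fits <- list()
  rhats <- c()
  for (k in seq_along(age_groups)) {
    ag <- age_groups[k]
    obs_ag <- data[data$age_group == ag, , drop = FALSE]
    if (nrow(obs_ag) == 0) stop_sexmort("no data for age group ", ag)
    totals_ag <- totals[totals$age_group == ag, , drop = FALSE]
    if (nrow(totals_ag) == 0) stop_sexmort("no totals for age group ", ag)
    fits[[ag]] <- fit_age_group(obs_ag, totals_ag, config, ag,
                                seed = config$seed + k - 1L)
    r <- fits[[ag]]$diagnostics$rhat
    names(r) <- paste0(ag, ":", names(r))
    rhats <- c(rhats, r)
  }
  status <- if (any(rhats > 1.05, na.rm = TRUE)) "warn" else "ok"
  structure(list(age_groups = fits, config = config, seed = config$seed,
                 diagnostics = list(rhat = rhats, status = status)),
            class = "posterior_trajectories")
}

#' @export
print.posterior_trajectories <- function(x, ...) {
  cat("Posterior trajectories:", length(x$age_groups), "age group(s),",
      x$config$n_draws, "draws\n")
  for (ag in names(x$age_groups)) {
    f <- x$age_groups[[ag]]
    cat(sprintf("  %s: %d countries x %d years\n", ag,
                length(f$countries), length(f$years)))
  }
  cat("convergence status:", x$diagnostics$status,
      sprintf("(max split-Rhat %.3f)\n", max(x$diagnostics$rhat)))
  invisible(x)
}

fit_age_group <- function(obs, totals, config, age_group, seed) {
  years <- config$years
  countries <- sort(unique(totals$country_code))
  C <- length(countries); Tn <- length(years)
  qmat <- matrix(NA_real_, C, Tn, dimnames = list(countries, years))
  qmat[cbind(match(totals$country_code, countries),
             match(totals$year, years))] <- totals$q_total
  if (anyNA(qmat))
    stop_sexmort("totals do not cover the full grid for age group ", age_group)
  logq <- log(qmat)

  oc <- match(obs$country_code, countries)
  if (anyNA(oc))
    stop_sexmort("observation countries missing from totals for ", age_group)
  ot <- nearest_year_index(obs$ref_year, years)
  cell <- oc + (ot - 1L) * C          # column-major index into C x Tn
  y <- log(obs$sex_ratio_obs)
  v <- obs$log_se_sampling^2
  src <- obs$source_type
  sources <- sort(unique(src))
  src_idx <- split(seq_along(y), src)
  n <- length(y)

  fixed <- config$fixed
  fixed_curve <- fixed$curve
  if (is.list(fixed_curve) && !inherits(fixed_curve, "global_curve"))
    fixed_curve <- fixed_curve[[age_group]]

  logq_obs <- logq[cbind(oc, ot)]
  if (is.null(fixed_curve)) {
    # default: knots at equally spaced quantiles of the observed
    # log-mortality values, so every segment has data support
    knots <- config$knots_logq %||%
      unique(unname(quantile(logq_obs, seq(0, 1, length.out = config$n_knots),
                             type = 7)))
    if (length(knots) < 2) knots <- c(knots[1] - 0.5, knots[1] + 0.5)
    K <- length(knots)
    A_obs <- interp_weights(knots, logq_obs)
    A_grid <- interp_weights(knots, as.vector(logq))
    P0 <- curve_prior_precision(K, config)
  } else {
    knots <- fixed_curve$knots_logq
    mu_obs_fixed <- log(expected_sex_ratio(exp(logq_obs), fixed_curve))
    mu_grid_fixed <- log(expected_sex_ratio(as.vector(qmat), fixed_curve))
  }

  set.seed(seed)
  sigma <- setNames(rep(0.05, length(SOURCE_TYPES)), SOURCE_TYPES)
  if (!is.null(fixed$sigma)) sigma[names(fixed$sigma)] <- fixed$sigma
  tau <- fixed$tau %||% 0.1
  rho <- fixed$rho %||% 0.5
  if (tau < 0) stop_sexmort("fixed tau must be >= 0")
  tau <- max(tau, 1e-8)
  D <- matrix(0, C, Tn)

  wfun <- function(sig) {
    w <- 1 / (v + sig[src]^2)
    if (any(!is.finite(w)))
      stop_sexmort("zero total observation variance; degenerate likelihood")
    w
  }
  w <- wfun(sigma)

  if (is.null(fixed_curve)) {
    Pp <- P0 + crossprod(A_obs, A_obs * w)
    beta <- drop(solve(Pp, crossprod(A_obs, w * y)))
    mu_obs <- drop(A_obs %*% beta)
  } else {
    beta <- NULL
    mu_obs <- mu_obs_fixed
  }

  thin <- config$thin %||% 1L
  n_iter <- config$n_warmup + config$n_draws * thin
  n_draws <- config$n_draws
  S_draws <- array(NA_real_, c(n_draws, C, Tn),
                   dimnames = list(NULL, countries, years))
  beta_draws <- if (is.null(fixed_curve)) matrix(NA_real_, n_draws, length(knots))
  hyper_draws <- matrix(NA_real_, n_draws, 2 + length(sources),
                        dimnames = list(NULL, c("tau", "rho",
                                                paste0("sigma_", sources))))
  # adaptive proposal log-scales
  ls <- c(tau = log(0.3), rho = log(0.5),
          setNames(rep(log(0.5), length(sources)), sources))
  adapt <- function(name, acc, it) {
    if (it <= config$n_warmup)
      ls[name] <<- ls[name] + (acc - 0.44) * 3 / (20 + it)
  }

  upd_sigma <- is.null(fixed$sigma)
  upd_tau <- is.null(fixed$tau)
  upd_rho <- is.null(fixed$rho) && Tn > 1
  upd_curve <- is.null(fixed_curve)

  for (it in seq_len(n_iter)) {
    ## --- sigma_j: adaptive MH on log scale --------------------------------
    if (upd_sigma) {
      e <- y - mu_obs - D[cell]
      for (j in sources) {
        ii <- src_idx[[j]]
        tgt <- function(s)
          sum(dnorm(e[ii], 0, sqrt(v[ii] + s^2), log = TRUE)) +
          half_normal_logdens(s, config$sigma_prior_scale)
        s_new <- sigma[j] * exp(rnorm(1, 0, exp(ls[j])))
        lr <- tgt(s_new) - tgt(sigma[j]) + log(s_new) - log(sigma[j])
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) sigma[j] <- s_new
        adapt(j, acc, it)
      }
      for (j in setdiff(SOURCE_TYPES, sources))
        sigma[j] <- abs(rnorm(1, 0, config$sigma_prior_scale))
      w <- wfun(sigma)
    }

    ## --- tau and rho: several cheap MH sweeps per Gibbs scan ---------------
    ## (tau gets a centered move plus an ancillarity-sufficiency
    ## interweaving rescale of delta; rho moves on the logit scale)
    for (sweep in 1:3) {
      if (upd_tau) {
        tgt_c <- function(tt)
          ar1_logdensity(D, rho, tt) +
          half_normal_logdens(tt, config$tau_prior_scale)
        t_new <- tau * exp(rnorm(1, 0, exp(ls["tau"])))
        lr <- tgt_c(t_new) - tgt_c(tau) + log(t_new) - log(tau)
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) tau <- t_new
        adapt("tau", acc, it)
        # interweaving: rescale delta with tau holding u = delta / tau fixed
        u_cell <- D[cell] / tau
        sd_tot <- 1 / sqrt(w)
        tgt_nc <- function(tt)
          sum(dnorm(y - mu_obs - tt * u_cell, 0, sd_tot, log = TRUE)) +
          half_normal_logdens(tt, config$tau_prior_scale)
        t_new <- tau * exp(rnorm(1, 0, exp(ls["tau"])))
        lr <- tgt_nc(t_new) - tgt_nc(tau) + log(t_new) - log(tau)
        if (is.finite(lr) && log(runif(1)) < lr) {
          D <- D * (t_new / tau)
          tau <- t_new
        }
      }
      if (upd_rho) {
        tgt_r <- function(r) ar1_logdensity(D, r, tau)
        z <- log(rho / (1 - rho)) + rnorm(1, 0, exp(ls["rho"]))
        r_new <- 1 / (1 + exp(-z))
        lr <- tgt_r(r_new) - tgt_r(rho) +
          log(r_new * (1 - r_new)) - log(rho * (1 - rho))
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) rho <- r_new
        adapt("rho", acc, it)
      }
    }

    ## --- delta: exact Gaussian conditional per country --------------------
    r_obs <- y - mu_obs
    Bfull <- numeric(C * Tn); bfull <- numeric(C * Tn)
    sB <- rowsum(w, cell); Bfull[as.integer(rownames(sB))] <- sB
    sb <- rowsum(w * r_obs, cell); bfull[as.integer(rownames(sb))] <- sb
    Bmat <- matrix(Bfull, C, Tn); bmat <- matrix(bfull, C, Tn)
    Q <- ar1_precision(Tn, rho, tau)
    for (c_i in seq_len(C)) {
      M <- Q
      diag(M) <- diag(M) + Bmat[c_i, ]
      R <- chol(M)
      mu_d <- backsolve(R, backsolve(R, bmat[c_i, ], transpose = TRUE))
      D[c_i, ] <- mu_d + backsolve(R, rnorm(Tn))
    }

    ## --- curve knot values: exact Gaussian conditional --------------------
    if (upd_curve) {
      r2 <- y - D[cell]
      Pp <- P0 + crossprod(A_obs, A_obs * w)
      R <- chol(Pp)
      mu_b <- backsolve(R, backsolve(R, crossprod(A_obs, w * r2),
                                     transpose = TRUE))
      beta <- drop(mu_b + backsolve(R, rnorm(length(knots))))
      mu_obs <- drop(A_obs %*% beta)
    }

    ## --- store -------------------------------------------------------------
    if (it > config$n_warmup && (it - config$n_warmup) %% thin == 0) {
      d <- (it - config$n_warmup) %/% thin
      mu_grid <- if (upd_curve) drop(A_grid %*% beta) else mu_grid_fixed
      S_draws[d, , ] <- exp(matrix(mu_grid, C, Tn) + D)
      if (upd_curve) beta_draws[d, ] <- beta
      hyper_draws[d, ] <- c(tau, rho, sigma[sources])
    }
  }

  rhat <- apply(hyper_draws, 2, split_rhat)
  list(age_group = age_group, countries = countries, years = years,
       qmat = qmat, knots_logq = knots,
       S = S_draws, beta = beta_draws, hyper = as.data.frame(hyper_draws),
       fixed_curve = if (!upd_curve) fixed_curve,
       diagnostics = list(rhat = rhat))
}

# Split-chain convergence statistic: one chain cut into `splits` segments.
split_rhat <- function(x, splits = 4) {
  m <- floor(length(x) / splits)
  if (m < 2) return(NA_real_)
  X <- matrix(x[seq_len(m * splits)], nrow = m)
  W <- mean(apply(X, 2, var))
  if (W == 0) return(1)
  B <- m * var(colMeans(X))
  sqrt(((m - 1) / m * W + B / m) / W)
}

# Posterior draws of the expected (curve-only) log sex ratio at given
# log total mortality values: matrix draw x length(logq).
curve_eval_draws <- function(fit_ag, logq) {
  if (!is.null(fit_ag$fixed_curve)) {
    mu <- log(expected_sex_ratio(exp(logq), fit_ag$fixed_curve))
    return(matrix(mu, nrow = nrow(fit_ag$hyper), ncol = length(logq),
                  byrow = TRUE))
  }
  A <- interp_weights(fit_ag$knots_logq, logq)
  fit_ag$beta %*% t(A)
}

#' Summarise posterior draws with a 90% uncertainty interval
#'
#' Median plus the 5th and 95th percentiles (for `level = 0.90`) using
#' the linear-interpolation quantile convention (R type 7).
#'
#' @param draws Numeric vector of at least 2 posterior draws.
#' @param level Interval coverage level (default 0.90).
#' @return Named numeric vector `median`, `lower`, `upper` of class
#'   `interval_summary`.
#' @export
summarize_ui <- function(draws, level = 0.90) {
  if (length(draws) < 2 || any(!is.finite(draws)))
    stop_sexmort("need at least 2 finite draws")
  a <- (1 - level) / 2
  q <- quantile(draws, c(a, 0.5, 1 - a), type = 7, names = FALSE)
  structure(c(median = q[2], lower = q[1], upper = q[3]),
            class = "interval_summary")
}

#' Fill in sex-specific mortality draws
#'
#' Applies [sex_split()] draw-wise: each posterior sex-ratio draw is
#' paired with a total-mortality value (the point estimate, or an
#' uncertainty draw chosen by an independent seeded shuffle when totals
#' draws are supplied), so the marginal uncertainty of `q_male` and
#' `q_female` reflects both the sex-ratio and the total-mortality
#' uncertainty.
#'
#' @param traj A [fit_model()] result.
#' @param totals Point totals data frame (`country_code, year,
#'   age_group, q_total`).
#' @param weights Data frame `country_code, year, age_group, w_male`
#'   with the male exposure share entering each age group (see
#'   [default_weights()]).
#' @param totals_draws Optional long data frame of totals uncertainty
#'   draws (`draw` column added).
#' @param seed Seed for the draw pairing shuffle (defaults to the run
#'   seed).
#' @return `traj` with arrays `q_male`, `q_female` added per age group.
#' @export
trajectories_to_sex_specific <- function(traj, totals, weights,
                                         totals_draws = NULL, seed = NULL) {
  stopifnot(inherits(traj, "posterior_trajectories"))
  seed <- seed %||% traj$seed
  set.seed(seed)
  for (ag in names(traj$age_groups)) {
    f <- traj$age_groups[[ag]]
    C <- length(f$countries); Tn <- length(f$years)
    n_draws <- dim(f$S)[1]
    Wm <- grid_matrix(weights, "w_male", f$countries, f$years, ag)
    if (anyNA(Wm)) stop_sexmort("missing weight for some country-year in ", ag)
    if (any(Wm <= 0 | Wm >= 1)) stop_sexmort("w_male must lie in (0, 1)")
    if (is.null(totals_draws)) {
      Qd <- array(rep(f$qmat, each = n_draws), c(n_draws, C, Tn))
    } else {
      td <- totals_draws[totals_draws$age_group == ag, , drop = FALSE]
      ids <- sort(unique(td$draw))
      perm <- sample(ids, n_draws, replace = length(ids) < n_draws)
      Qd <- array(NA_real_, c(n_draws, C, Tn))
      for (d in seq_len(n_draws)) {
        tdd <- td[td$draw == perm[d], , drop = FALSE]
        Qd[d, , ] <- grid_matrix(tdd, "q_total", f$countries, f$years, ag)
      }
      if (anyNA(Qd)) stop_sexmort("totals draws do not cover the grid for ", ag)
    }
    Wb <- array(rep(Wm, each = n_draws), c(n_draws, C, Tn))
    q_female <- Qd / (Wb * f$S + 1 - Wb)
    q_male <- f$S * q_female
    if (any(q_male >= 1))
      stop_sexmort("inconsistent inputs: implied q_male >= 1 in ", ag)
    traj$age_groups[[ag]]$q_male <- q_male
    traj$age_groups[[ag]]$q_female <- q_female
    traj$age_groups[[ag]]$q_total_draws <- Qd
  }
  traj
}

# Long data frame -> country x year matrix for one age group.
grid_matrix <- function(df, col, countries, years, age_group) {
  df <- df[df$age_group == age_group, , drop = FALSE]
  m <- matrix(NA_real_, length(countries), length(years),
              dimnames = list(countries, years))
  i <- match(df$country_code, countries)
  j <- match(df$year, years)
  ok <- !is.na(i) & !is.na(j)
  m[cbind(i[ok], j[ok])] <- df[[col]][ok]
  m
}

#' Posterior summary table of sex ratios
#'
#' @param traj A [fit_model()] result.
#' @return Data frame with one row per (country, year, age group) and
#'   `median`, `lower`, `upper` columns for the sex ratio (90% UI).
#' @export
posterior_summary <- function(traj) {
  stopifnot(inherits(traj, "posterior_trajectories"))
  out <- list()
  for (ag in names(traj$age_groups)) {
    f <- traj$age_groups[[ag]]
    qs <- apply(f$S, c(2, 3), quantile, probs = c(0.05, 0.5, 0.95),
                type = 7, names = FALSE)
    out[[ag]] <- data.frame(
      country_code = rep(f$countries, times = length(f$years)),
      year = rep(f$years, each = length(f$countries)),
      age_group = ag,
      median = as.vector(qs[2, , ]),
      lower = as.vector(qs[1, , ]),
      upper = as.vector(qs[3, , ]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
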