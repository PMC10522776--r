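## Deterministic demographic transforms: sex-specific rates from totals and
## ratios, expected vs estimated female mortality under the male-reference
## convention, excess female mortality and deaths, outlier flags, and
## survival to age 25.

#' Split total mortality into sex-specific probabilities
#'
#' Given the total (both-sex) probability of dying, the male:female sex
#' ratio, and the male share of exposure entering the age group, solves
#' the exposure-weighted conservation identity
#' `w_male * q_male + (1 - w_male) * q_female = q_total` together with
#' `q_male = s * q_female`:
#' `q_female = q_total / (w_male * s + 1 - w_male)`.
#'
#' @param q_total Total probability of dying, in (0, 1); vectorised.
#' @param s Sex ratio (male over female), positive.
#' @param w_male Male exposure share, in (0, 1).
#' @return List with `q_male` and `q_female`.
#' @export
sex_split <- function(q_total, s, w_male) {
  if (any(!is.finite(q_total)) || any(q_total <= 0) || any(q_total >= 1))
    stop_sexmort("q_total must lie strictly in (0, 1)")
  if (any(!is.finite(s)) || any(s <= 0)) stop_sexmort("s must be positive")
  if (any(!is.finite(w_male)) || any(w_male <= 0) || any(w_male >= 1))
    stop_sexmort("w_male must lie strictly in (0, 1)")
  q_female <- q_total / (w_male * s + 1 - w_male)
  q_male <- s * q_female
  if (any(q_male >= 1))
    stop_sexmort("inconsistent inputs: implied q_male >= 1")
  list(q_male = q_male, q_female = q_female)
}

#' Expected and estimated female mortality and the excess rate
#'
#' Male mortality is the reference: the estimated male rate comes from
#' splitting the total with the estimated sex ratio; the estimated and
#' expected female rates divide that same male rate by the estimated
#' and expected ratios.  Excess female mortality is their difference
#' (positive when females die more than expected at this total
#' mortality level); the identity
#' `q_female_est / q_female_exp = s_exp / s_est` holds exactly.
#'
#' @param q_total Total probability of dying, in (0, 1).
#' @param s_est Estimated sex ratio (posterior, country-specific).
#' @param s_exp Expected sex ratio (global curve at the same total
#'   mortality).
#' @param w_male Male exposure share.
#' @return List with `q_female_est`, `q_female_exp`, `excess_rate`
#'   (same scale as `q_total`; multiply by 1000 to report per 1000).
#' @export
excess_female_rate <- function(q_total, s_est, s_exp, w_male) {
  if (any(!is.finite(s_exp)) || any(s_exp <= 0))
    stop_sexmort("s_exp must be positive")
  sp <- sex_split(q_total, s_est, w_male)
  q_female_est <- sp$q_male / s_est
  q_female_exp <- sp$q_male / s_exp
  list(q_female_est = q_female_est, q_female_exp = q_female_exp,
       excess_rate = q_female_est - q_female_exp)
}

#' Excess female deaths from the estimated-to-expected ratio
#'
#' Converts estimated female deaths into excess deaths draw-wise:
#' `excess = female_deaths_est * (1 - 1 / R)` where `R` is the
#' estimated-to-expected female mortality ratio; negative when `R < 1`
#' (female advantage).
#'
#' @param female_deaths_est Estimated female death count, `>= 0`.
#' @param ratio_est_exp Draws (or scalars) of the estimated-to-expected
#'   female mortality ratio, positive.
#' @return Excess death count draws.
#' @export
excess_deaths <- function(female_deaths_est, ratio_est_exp) {
  if (any(!is.finite(female_deaths_est)) || any(female_deaths_est < 0))
    stop_sexmort("female_deaths_est must be >= 0")
  if (any(!is.finite(ratio_est_exp)) || any(ratio_est_exp <= 0))
    stop_sexmort("ratio_est_exp must be positive")
  female_deaths_est * (1 - 1 / ratio_est_exp)
}

#' Two-condition outlier rule for excess female mortality
#'
#' A country-year is flagged as having an outlying sex ratio when
#' (1) the posterior probability that excess female mortality is
#' greater than zero, or the probability that it is less than zero, is
#' at least `prob_threshold` (default 95%), and (2) the absolute median
#' excess exceeds `magnitude_threshold` (default one death per 1000,
#' i.e. 0.001 on the probability scale).
#'
#' @param excess_draws Numeric vector of at least 100 posterior draws
#'   of the excess female mortality rate (per 1, not per 1000).
#' @param prob_threshold Posterior-probability threshold.
#' @param magnitude_threshold Median-magnitude threshold (per 1).
#' @return List with `prob_excess_positive`, `prob_excess_negative`,
#'   `outlier_flag`.
#' @export
flag_outlier <- function(excess_draws, prob_threshold = 0.95,
                         magnitude_threshold = 0.001) {
  if (length(excess_draws) < 100)
    stop_sexmort("need at least 100 draws to apply the outlier rule")
  p_pos <- mean(excess_draws > 0)
  p_neg <- mean(excess_draws < 0)
  med <- median(excess_draws)
  list(prob_excess_positive = p_pos,
       prob_excess_negative = p_neg,
       outlier_flag = max(p_pos, p_neg) >= prob_threshold &&
         abs(med) > magnitude_threshold)
}

#' Survival from birth to age 25
#'
#' Product of the age-interval survival probabilities:
#' `(1 - q(0-4)) * (1 - q(5-14)) * (1 - q(15-24))`.
#'
#' @param q_0_4,q_5_14,q_15_24 Probabilities of dying in each age
#'   interval, in `[0, 1]`; vectorised.
#' @return Probability of surviving to the 25th birthday.
#' @export
survival_to_25 <- function(q_0_4, q_5_14, q_15_24) {
  qs <- cbind(q_0_4, q_5_14, q_15_24)
  if (any(!is.finite(qs)) || any(qs < 0) || any(qs > 1))
    stop_sexmort("all q must lie in [0, 1]")
  unname((1 - q_0_4) * (1 - q_5_14) * (1 - q_15_24))
}

#' Default sex-split exposure weights
#'
#' Male exposure share at entry into each age group: for 0-4 the share
#' of male births, `SRB / (1 + SRB)` (default sex ratio at birth 1.05);
#' for the older groups the male population share (same default in the
#' absence of country values).
#'
#' @param totals Data frame with `country_code, year, age_group` (the
#'   grid to cover).
#' @param srb Sex ratio at birth.
#' @param w_male_older Male population share for ages 5+.
#' @return Data frame `country_code, year, age_group, w_male`.
#' @export
default_weights <- function(totals, srb = 1.05, w_male_older = srb / (1 + srb)) {
  w <- ifelse(totals$age_group == "0-4", srb / (1 + srb), w_male_older)
  data.frame(country_code = totals$country_code, year = totals$year,
             age_group = totals$age_group, w_male = w,
             stringsAsFactors = FALSE)
}

#' Excess female mortality results per country-year
#'
#' Draw-wise derivation of the full excess-mortality output: estimated
#' and expected female mortality (male reference), the
#' estimated-to-expected ratio, the excess rate (reported per 1000),
#' excess deaths when female death counts are available, tail
#' probabilities, and the two-condition outlier flag.
#'
#' @param traj A [fit_model()] result.
#' @param weights Sex-split weights (see [default_weights()]).
#' @param female_deaths Optional data frame `country_code, year,
#'   age_group, deaths_female` of estimated female death counts.
#' @param prob_threshold,magnitude_threshold Outlier-rule thresholds
#'   (see [flag_outlier()]).
#' @return Data frame with one row per (country, year, age group):
#'   medians and 90% intervals for `q_female_est`, `q_female_exp`,
#'   `ratio_est_exp`, `excess_rate_per1000`, `excess_deaths` (if
#'   available), plus `prob_excess_positive`, `prob_excess_negative`,
#'   `outlier_flag`.
#' @export
derive_excess <- function(traj, weights, female_deaths = NULL,
                          prob_threshold = 0.95,
                          magnitude_threshold = 0.001) {
  stopifnot(inherits(traj, "posterior_trajectories"))
  out <- list()
  for (ag in names(traj$age_groups)) {
    f <- traj$age_groups[[ag]]
    C <- length(f$countries); Tn <- length(f$years)
    n_draws <- dim(f$S)[1]
    Wm <- grid_matrix(weights, "w_male", f$countries, f$years, ag)
    if (anyNA(Wm)) stop_sexmort("missing weight for some country-year in ", ag)
    logq <- as.vector(log(f$qmat))
    mu_exp <- curve_eval_draws(f, logq)           # draws x (C*Tn)
    S_flat <- matrix(f$S, n_draws, C * Tn)
    s_exp <- exp(mu_exp)
    Qv <- matrix(rep(as.vector(f$qmat), each = n_draws), n_draws)
    Wv <- matrix(rep(as.vector(Wm), each = n_draws), n_draws)
    q_f_est <- Qv / (Wv * S_flat + 1 - Wv)
    q_m_est <- S_flat * q_f_est
    q_f_exp <- q_m_est / s_exp
    ratio <- s_exp / S_flat                        # = q_f_est / q_f_exp
    excess <- q_f_est - q_f_exp

    qsum <- function(M) apply(M, 2, quantile, probs = c(0.05, 0.5, 0.95),
                              type = 7, names = FALSE)
    s1 <- qsum(q_f_est); s2 <- qsum(q_f_exp); s3 <- qsum(ratio)
    s4 <- qsum(excess)
    p_pos <- colMeans(excess > 0)
    p_neg <- colMeans(excess < 0)
    flag <- pmax(p_pos, p_neg) >= prob_threshold &
      abs(s4[2, ]) > magnitude_threshold

    res <- data.frame(
      country_code = rep(f$countries, times = Tn),
      year = rep(f$years, each = C),
      age_group = ag,
      q_female_est = s1[2, ], q_female_est_lower = s1[1, ],
      q_female_est_upper = s1[3, ],
      q_female_exp = s2[2, ], q_female_exp_lower = s2[1, ],
      q_female_exp_upper = s2[3, ],
      ratio_est_exp = s3[2, ], ratio_est_exp_lower = s3[1, ],
      ratio_est_exp_upper = s3[3, ],
      excess_rate_per1000 = 1000 * s4[2, ],
      excess_rate_per1000_lower = 1000 * s4[1, ],
      excess_rate_per1000_upper = 1000 * s4[3, ],
      prob_excess_positive = p_pos,
      prob_excess_negative = p_neg,
      outlier_flag = flag,
      stringsAsFactors = FALSE)

    if (!is.null(female_deaths)) {
      Dm <- grid_matrix(female_deaths, "deaths_female", f$countries,
                        f$years, ag)
      Dv <- matrix(rep(as.vector(Dm), each = n_draws), n_draws)
      xd <- Dv * (1 - 1 / ratio)
      s5 <- qsum(xd)
      res$excess_deaths <- s5[2, ]
      res$excess_deaths_lower <- s5[1, ]
      res$excess_deaths_upper <- s5[3, ]
    }
    out[[ag]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
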