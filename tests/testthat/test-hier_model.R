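test_that("expected sex ratio interpolates log-linearly with flat tails", {
  cv <- global_curve("0-4", knots_logq = c(-3, -1),
                     values_logs = c(0.20, 0.05))
  # at a knot: exact
  expect_equal(expected_sex_ratio(exp(-3), cv), exp(0.20), tolerance = 1e-12)
  # midpoint: hand linear interpolation
  expect_equal(expected_sex_ratio(exp(-2), cv), exp(0.125), tolerance = 1e-12)
  expect_equal(exp(0.125), 1.13315, tolerance = 1e-5)
  # flat extrapolation below the first knot
  expect_equal(expected_sex_ratio(exp(-5), cv), exp(0.20), tolerance = 1e-12)
  expect_equal(exp(0.20), 1.22140, tolerance = 1e-5)
  expect_error(expected_sex_ratio(1.5, cv), "0, 1")
  expect_error(global_curve("0-4", c(-1, -3), c(0, 0)), "increasing")
})

test_that("expected sex ratio is continuous and collinear-knot invariant", {
  cv <- global_curve("5-14", c(-6, -4, -2), c(0.1, 0.3, 0.15))
  # insert a collinear knot at -5 (midpoint of the first segment)
  cv2 <- global_curve("5-14", c(-6, -5, -4, -2), c(0.1, 0.2, 0.3, 0.15))
  q <- exp(seq(-7, -1, length.out = 101))
  expect_equal(expected_sex_ratio(q, cv), expected_sex_ratio(q, cv2),
               tolerance = 1e-12)
  # continuity across knots
  eps <- 1e-9
  for (k in c(-6, -4, -2))
    expect_equal(expected_sex_ratio(exp(k - eps), cv),
                 expected_sex_ratio(exp(k + eps), cv), tolerance = 1e-6)
})

test_that("multiplier log density matches the dense Gaussian oracle", {
  # length-1, delta = 0, tau = 1: standard Normal at 0
  s1 <- multiplier_series("AAA", "0-4", 0, rho = 0.5, tau = 1)
  expect_equal(multiplier_logdensity(s1), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(-0.5 * log(2 * pi), -0.918939, tolerance = 1e-6)

  set.seed(31)
  for (len in 1:5) {
    delta <- rnorm(len, 0, 0.2)
    for (pars in list(c(0.3, 0.1), c(0.9, 0.05), c(0.99, 1))) {
      s <- multiplier_series("AAA", "0-4", delta, rho = pars[1],
                             tau = pars[2])
      expect_equal(multiplier_logdensity(s),
                   dense_ar1_logdensity(delta, pars[1], pars[2]),
                   tolerance = 1e-8)
    }
  }

  # rho -> 0 limit: independent Normals
  delta <- c(0.1, -0.05, 0.2)
  s <- multiplier_series("AAA", "0-4", delta, rho = 1e-9, tau = 0.3)
  expect_equal(multiplier_logdensity(s),
               sum(dnorm(delta, 0, 0.3, log = TRUE)), tolerance = 1e-6)

  # tau = 0: point mass at zero
  s0 <- multiplier_series("AAA", "0-4", c(0.1, 0), rho = 0.5, tau = 0)
  expect_identical(multiplier_logdensity(s0), -Inf)
  expect_error(multiplier_series("AAA", "0-4", 0, rho = 1.2, tau = 1),
               "rho")
})

test_that("observation likelihood combines sampling and non-sampling variance", {
  em <- error_model(c(VR = 0.025, SBH = 0.075))
  rec <- list(sex_ratio_obs = exp(0.1), log_se_sampling = 0.02,
              source_type = "VR")
  # Normal(0.1; 0, sqrt(0.0004 + 0.000625))
  expect_equal(observation_loglik(rec, 1, em),
               dnorm(0.1, 0, sqrt(0.02^2 + 0.025^2), log = TRUE),
               tolerance = 1e-12)

  # zero residual, unit total variance
  rec2 <- list(sex_ratio_obs = 1.3, log_se_sampling = sqrt(1 - 0.025^2),
               source_type = "VR")
  expect_equal(observation_loglik(rec2, 1.3, em), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  # direct density arithmetic at v = 0.0004, sigma^2 = 0.0021
  em2 <- error_model(c(VR = sqrt(0.0021)))
  rec3 <- list(sex_ratio_obs = exp(0.1), log_se_sampling = 0.02,
               source_type = "VR")
  manual <- -0.5 * log(2 * pi) - log(0.05) - 0.5 * (0.1 / 0.05)^2
  expect_equal(observation_loglik(rec3, 1, em2), manual, tolerance = 1e-12)
  expect_equal(manual, 0.0767937, tolerance = 1e-6)

  # inflating the non-sampling SD flattens the likelihood gradient
  grad <- function(sig) {
    e <- error_model(c(VR = sig))
    h <- 1e-6
    (observation_loglik(rec, 1 + h, e) - observation_loglik(rec, 1 - h, e)) /
      (2 * h)
  }
  expect_lt(abs(grad(0.05)), abs(grad(0.025)))

  # degenerate likelihood
  rec0 <- list(sex_ratio_obs = 1, log_se_sampling = 0, source_type = "VR")
  expect_error(observation_loglik(rec0, 1, error_model(c(VR = 0))),
               "positive")
})

test_that("log posterior equals the sum of its components and is additive", {
  cfg <- model_config(years = 2000:2004, seed = 1)
  curve <- global_curve("0-4", c(-5, -3), c(0.15, 0.05))
  countries <- c("AAA", "BBB")
  D <- matrix(c(0.05, 0.02, -0.01, 0, 0.01,
                -0.03, -0.02, 0.01, 0.02, 0.04),
              nrow = 2, byrow = TRUE, dimnames = list(countries, 2000:2004))
  sigma <- c(VR = 0.03, SBH = 0.08)
  params <- list(curves = list("0-4" = curve),
                 delta = list("0-4" = D),
                 hyper = list("0-4" = list(rho = 0.8, tau = 0.1)),
                 error_model = error_model(sigma))
  totals <- expand.grid(country_code = countries, year = 2000:2004,
                        stringsAsFactors = FALSE)
  totals$age_group <- "0-4"
  totals$q_total <- exp(seq(-4.5, -3.5, length.out = nrow(totals)))

  obs <- as_obs_table(data.frame(
    country_code = c("AAA", "AAA", "BBB", "BBB", "AAA"),
    ref_year = c(2000, 2002, 2001, 2004, 2003.4),
    age_group = "0-4",
    source_type = c("VR", "SBH", "VR", "VR", "SBH"),
    series_id = paste0("s", 1:5),
    sex_ratio_obs = c(1.12, 1.3, 1.05, 1.2, 0.9),
    log_se_sampling = c(0.03, 0.1, 0.05, 0.04, 0.12),
    stringsAsFactors = FALSE))

  lp <- log_posterior(params, obs, totals, cfg)

  # independent component sum
  expect_loglik <- 0
  for (i in seq_len(nrow(obs))) {
    rec <- as.list(obs[i, ])
    t_idx <- which.min(abs(cfg$years - rec$ref_year))
    q <- totals$q_total[totals$country_code == rec$country_code &
                          totals$year == cfg$years[t_idx]]
    s_model <- expected_sex_ratio(q, curve) * exp(D[rec$country_code, t_idx])
    expect_loglik <- expect_loglik +
      dnorm(log(rec$sex_ratio_obs), log(s_model),
            sqrt(rec$log_se_sampling^2 + sigma[[rec$source_type]]^2),
            log = TRUE)
  }
  prior_part <- dense_ar1_logdensity(D[1, ], 0.8, 0.1) +
    dense_ar1_logdensity(D[2, ], 0.8, 0.1) +
    dnorm(0.15, 0, cfg$first_knot_sd, log = TRUE) +
    dnorm(0.05, 0, cfg$curve_value_sd, log = TRUE) +
    dnorm(0.1, 0, cfg$tau_prior_scale, log = TRUE) + log(2) +
    sum(dnorm(sigma, 0, cfg$sigma_prior_scale, log = TRUE) + log(2))
  expect_equal(lp, expect_loglik + prior_part, tolerance = 1e-8)

  # empty table: prior-only value
  lp0 <- log_posterior(params, obs[0, ], totals, cfg)
  expect_equal(lp0, prior_part, tolerance = 1e-8)

  # additivity: duplicating one observation shifts by exactly its loglik
  dup <- as.data.frame(obs)
  dup$series_id[5] <- "dup"
  both <- as_obs_table(rbind(as.data.frame(obs), dup[5, ]))
  expect_equal(log_posterior(params, both, totals, cfg) - lp,
               lp - log_posterior(params, obs[-5, ], totals, cfg),
               tolerance = 1e-8)
})
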