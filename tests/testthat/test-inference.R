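test_that("interval summary follows the linear-interpolation convention", {
  expect_equal(unclass(summarize_ui(rep(3.7, 10))),
               c(median = 3.7, lower = 3.7, upper = 3.7))
  s <- summarize_ui(1:100)
  expect_equal(s[["lower"]], 5.95)
  expect_equal(s[["upper"]], 95.05)
  expect_equal(s[["median"]], 50.5)
  set.seed(2)
  sym <- summarize_ui(rnorm(20000))
  expect_lt(abs(sym[["median"]]), 3 / sqrt(20000) * 1.25)
  expect_error(summarize_ui(numeric(0)), "draws")
  expect_error(summarize_ui(5), "draws")
})

test_that("reduced conjugate case matches the closed-form posterior", {
  # curve and variances fixed, one country-year, one observation:
  # posterior mean of delta is (tau^2 / (tau^2 + v)) * (y - log f(Q))
  curve <- global_curve("0-4", c(-5, -3), c(0.2, 0.1))
  tau <- 0.15; v <- 0.08^2
  totals <- data.frame(country_code = "AAA", year = 2010, age_group = "0-4",
                       q_total = exp(-4))
  y <- log(1.4)
  obs <- as_obs_table(data.frame(
    country_code = "AAA", ref_year = 2010, age_group = "0-4",
    source_type = "VR", series_id = "s1", sex_ratio_obs = exp(y),
    log_se_sampling = sqrt(v), stringsAsFactors = FALSE))
  cfg <- model_config(years = 2010, n_draws = 4000, n_warmup = 200, seed = 8,
                      fixed = list(curve = curve, tau = tau, rho = 0.9,
                                   sigma = c(VR = 0, FBH = 0, SBH = 0,
                                             CENSUS = 0)))
  fit <- fit_model(obs, totals, cfg)
  f <- fit$age_groups[["0-4"]]
  delta_draws <- log(f$S[, 1, 1]) - log(expected_sex_ratio(exp(-4), curve))
  resid <- y - log(expected_sex_ratio(exp(-4), curve))
  post_mean <- tau^2 / (tau^2 + v) * resid
  post_sd <- sqrt(1 / (1 / tau^2 + 1 / v))
  expect_lt(abs(mean(delta_draws) - post_mean), 4 * post_sd / sqrt(4000))
  expect_lt(abs(sd(delta_draws) - post_sd), 4 * post_sd / sqrt(2 * 4000))
})

test_that("sampler is deterministic under a fixed seed", {
  cfg <- tiny_sim(seed = 3)
  tr <- simulate_truth(simulate_total_mortality(cfg), cfg)
  obs <- simulate_observations(tr, cfg)
  mc <- model_config(years = cfg$years, n_draws = 50, n_warmup = 50, seed = 4)
  f1 <- fit_model(obs, tr$totals, mc)
  f2 <- fit_model(obs, tr$totals, mc)
  expect_identical(f1$age_groups[["0-4"]]$S, f2$age_groups[["0-4"]]$S)
  expect_identical(f1$age_groups[["0-4"]]$hyper, f2$age_groups[["0-4"]]$hyper)
})

test_that("near-noiseless data pin the posterior to the truth", {
  # tau_truth = 0 and tiny observation variances: posterior median S
  # within 1% of the true curve value everywhere
  cfg <- tiny_sim(seed = 12, n_countries = 6, years = 2005:2012,
                  tau_truth = 0, obs_per_country_year = 2,
                  sampling_se_range = list(VR = c(0.01, 0.01),
                                           FBH = c(0.01, 0.01),
                                           SBH = c(0.01, 0.01),
                                           CENSUS = c(0.01, 0.01)),
                  sigma_by_source = c(VR = 0, FBH = 0, SBH = 0, CENSUS = 0))
  tr <- simulate_truth(simulate_total_mortality(cfg), cfg)
  obs <- simulate_observations(tr, cfg)
  mc <- model_config(years = cfg$years, n_draws = 400, n_warmup = 300,
                     seed = 2,
                     fixed = list(tau = 1e-3, rho = 0.9,
                                  sigma = c(VR = 0, FBH = 0, SBH = 0,
                                            CENSUS = 0)))
  fit <- fit_model(obs, tr$totals, mc)
  s <- posterior_summary(fit)
  m <- merge(s, tr$s_true, by = c("country_code", "year", "age_group"))
  # only cells with at least one observation are pinned by data
  seen <- unique(paste(obs$country_code, obs$ref_year))
  m <- m[paste(m$country_code, m$year) %in% seen, ]
  expect_gt(nrow(m), 20)
  expect_lt(max(abs(m$median / m$s_true - 1)), 0.01)
})

test_that("countries without data track the curve with wider intervals", {
  cfg <- tiny_sim(seed = 21, n_countries = 10, years = 2000:2011,
                  obs_per_country_year = 2)
  tr <- simulate_truth(simulate_total_mortality(cfg), cfg)
  obs <- simulate_observations(tr, cfg)
  # drop every observation from country S02
  obs_drop <- obs[obs$country_code != "S02", , drop = FALSE]
  class(obs_drop) <- class(obs)
  mc <- model_config(years = cfg$years, n_draws = 400, n_warmup = 300,
                     seed = 5)
  fit <- fit_model(obs_drop, tr$totals, mc)
  s <- posterior_summary(fit)
  f <- fit$age_groups[["0-4"]]
  # no-data country: median tracks the fitted expected curve
  s2 <- s[s$country_code == "S02", ]
  curve_med <- exp(apply(sexmort:::curve_eval_draws(
    f, log(tr$totals$q_total[tr$totals$country_code == "S02"])), 2, median))
  expect_lt(median(abs(log(s2$median / curve_med))), 0.05)
  # and its intervals are wider than the data-rich countries' on average
  width <- with(s, tapply(log(upper / lower), country_code, mean))
  expect_gt(width[["S02"]], max(width[names(width) != "S02"]))
})

test_that("sex-specific draws conserve the total and respond to inputs", {
  cfg <- tiny_sim(seed = 6, n_countries = 4, years = 2000:2005)
  tr <- simulate_truth(simulate_total_mortality(cfg), cfg)
  obs <- simulate_observations(tr, cfg)
  mc <- model_config(years = cfg$years, n_draws = 200, n_warmup = 150,
                     seed = 7)
  fit <- fit_model(obs, tr$totals, mc)
  weights <- default_weights(tr$totals)
  fx <- trajectories_to_sex_specific(fit, tr$totals, weights)
  f <- fx$age_groups[["0-4"]]
  w <- 1.05 / 2.05
  # conservation per draw against the point totals
  lhs <- w * f$q_male + (1 - w) * f$q_female
  rhs <- array(rep(f$qmat, each = dim(f$S)[1]), dim(f$S))
  expect_lt(max(abs(lhs - rhs)), 1e-12)

  # unit sex ratio: q_male = q_female = q_total, draw-wise
  fit1 <- fit
  fit1$age_groups[["0-4"]]$S[] <- 1
  fx1 <- trajectories_to_sex_specific(fit1, tr$totals, weights)
  expect_lt(max(abs(fx1$age_groups[["0-4"]]$q_male - rhs)), 1e-12)
  expect_lt(max(abs(fx1$age_groups[["0-4"]]$q_female - rhs)), 1e-12)

  # propagating totals uncertainty widens the female-mortality interval
  nd <- dim(f$S)[1]
  draws_wide <- do.call(rbind, lapply(seq_len(nd), function(d) {
    z <- as.data.frame(tr$totals)
    z$draw <- d
    set.seed(1000 + d)
    z$q_total <- pmin(z$q_total * exp(rnorm(nrow(z), 0, 0.1)), 0.5)
    z
  }))
  fxw <- trajectories_to_sex_specific(fit, tr$totals, weights,
                                      totals_draws = draws_wide)
  iw <- function(x) {
    q <- apply(matrix(x$age_groups[["0-4"]]$q_female,
                      nd, length(f$countries) * length(f$years)),
               2, quantile, c(0.05, 0.95))
    mean(q[2, ] - q[1, ])
  }
  expect_gt(iw(fxw), iw(fx))
})
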