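test_that("write/load round trip is lossless for valid records", {
  tab <- as_obs_table(make_obs_df())
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(tab, path)
  back <- load_observations(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(nrow(attr(back, "rejections")), 0)
})

test_that("invalid rows are rejected with reasons, valid rows parsed", {
  df <- make_obs_df()
  df$sex_ratio_obs[2] <- -1
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tab <- load_observations(path)
  expect_equal(nrow(tab), 2)
  rej <- attr(tab, "rejections")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "sex_ratio_obs")
  # strict construction errors instead
  expect_error(as_obs_table(df), "sex_ratio_obs")
})

test_that("a mixed-source fixture parses into correct records", {
  tab <- as_obs_table(make_obs_df(3))
  expect_s3_class(tab, "obs_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$source_type, c("VR", "SBH", "CENSUS"))
  expect_equal(tab$age_group, c("0-4", "5-14", "15-24"))
  expect_true(all(tab$sex_ratio_obs > 0))
})

test_that("record invariants are enforced", {
  base <- make_obs_df(1)
  bad_year <- base; bad_year$ref_year <- 1950
  expect_error(as_obs_table(bad_year), "ref_year")
  bad_ag <- base; bad_ag$age_group <- "25-29"
  expect_error(as_obs_table(bad_ag), "age_group")
  bad_src <- base; bad_src$source_type <- "DHS"
  expect_error(as_obs_table(bad_src), "source_type")
  dup <- rbind(base, base)
  expect_error(as_obs_table(dup), "duplicate")
  # a missing SE is derived from counts; without counts the row is invalid
  no_se <- base; no_se$log_se_sampling <- NA_real_
  no_se$deaths_male <- 200; no_se$deaths_female <- 200
  tab <- as_obs_table(no_se)
  expect_equal(tab$log_se_sampling, sqrt(1 / 200 + 1 / 200))
  no_se$deaths_male <- NA_real_
  expect_error(as_obs_table(no_se), "log_se_sampling")
})

test_that("sampling variance follows the delta-method formula", {
  expect_equal(compute_sampling_variance(100, 100), 0.02)
  expect_lt(compute_sampling_variance(1e9, 1e9), 1e-8)
  expect_error(compute_sampling_variance(0, 50), "positive")
  # symmetry and monotonicity
  for (pair in list(c(13, 412), c(5, 5), c(1000, 7))) {
    expect_equal(compute_sampling_variance(pair[1], pair[2]),
                 compute_sampling_variance(pair[2], pair[1]))
  }
  expect_gt(compute_sampling_variance(50, 100),
            compute_sampling_variance(60, 100))
})

test_that("fine-to-reporting aggregation uses conditional survival products", {
  res <- aggregate_fine_to_reporting(
    c("5-9" = 0.010, "10-14" = 0.006),
    c("5-9" = 0.008, "10-14" = 0.005), "5-14")
  expect_equal(res$q_male, 1 - 0.99 * 0.994, tolerance = 1e-12)
  expect_equal(res$q_male, 0.015940, tolerance = 1e-4)
  expect_equal(res$q_female, 0.012960, tolerance = 1e-4)
  expect_equal(res$sex_ratio, 1.2299, tolerance = 1e-4)

  # symmetry: equal inputs give ratio exactly 1; swapping sexes inverts it
  eq <- aggregate_fine_to_reporting(c("U1" = 0.03, "1-4" = 0.01),
                                    c("U1" = 0.03, "1-4" = 0.01), "0-4")
  expect_identical(eq$sex_ratio, 1)
  a <- aggregate_fine_to_reporting(c("15-19" = 0.02, "20-24" = 0.03),
                                   c("15-19" = 0.015, "20-24" = 0.022),
                                   "15-24")
  b <- aggregate_fine_to_reporting(c("15-19" = 0.015, "20-24" = 0.022),
                                   c("15-19" = 0.02, "20-24" = 0.03),
                                   "15-24")
  expect_equal(a$sex_ratio, 1 / b$sex_ratio, tolerance = 1e-12)

  # single fine group equal to the reporting group passes through
  pt <- aggregate_fine_to_reporting(c("0-4" = 0.04), c("0-4" = 0.035), "0-4")
  expect_equal(pt$q_male, 0.04)
  expect_equal(pt$q_female, 0.035)

  expect_error(aggregate_fine_to_reporting(c("5-9" = 0.01),
                                           c("5-9" = 0.01), "5-14"),
               "missing fine group")
  expect_error(aggregate_fine_to_reporting(c("5-9" = 1.2, "10-14" = 0.01),
                                           c("5-9" = 0.01, "10-14" = 0.01),
                                           "5-14"),
               "probabilities")
})

test_that("extreme filtering removes exactly the out-of-bounds records", {
  df <- make_obs_df(3)
  df$sex_ratio_obs <- c(6.0, 1.2, 0.1)
  tab <- as_obs_table(df)
  res <- filter_extremes(tab, lower = 0.2, upper = 5.0)
  expect_equal(nrow(res$table), 1)
  expect_equal(res$table$sex_ratio_obs, 1.2)
  expect_equal(unname(res$removed[c("0-4", "5-14", "15-24")]), c(1, 0, 1))

  inside <- filter_extremes(as_obs_table(make_obs_df(3)))
  expect_equal(nrow(inside$table), 3)
  expect_true(all(inside$removed == 0))

  expect_error(filter_extremes(tab, lower = 5, upper = 0.2), "bounds")
})

test_that("removed fraction is reported correctly on a constructed table", {
  # 100 records in one age group, exactly 2 outside the bounds
  n <- 100
  df <- data.frame(
    country_code = "AAA", ref_year = 2000 + seq_len(n) / 1000,
    age_group = "0-4", source_type = "VR",
    series_id = paste0("s", seq_len(n)),
    sex_ratio_obs = c(rep(1.1, n - 2), 8, 0.05),
    log_se_sampling = 0.05, deaths_male = NA_real_, deaths_female = NA_real_,
    stringsAsFactors = FALSE)
  res <- filter_extremes(as_obs_table(df))
  expect_equal(unname(res$removed["0-4"]), 0.02)
  expect_lt(unname(res$removed["0-4"]), 0.024)
  expect_equal(nrow(res$table), 98)
  # order preserved
  expect_equal(res$table$series_id, paste0("s", seq_len(98)))
})
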