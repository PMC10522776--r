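## Out-of-sample validation: hold out ~20% of observations, refit, and report
## predictive-interval coverage and error metrics.

#' Split an observation table into training and holdout sets
#'
#' Random holdout stratified by age group (per-group sizes by largest
#' remainder so the total equals `round(fraction * n)`), or a
#' leave-last-years-out split for assessing short-term projection.
#' The two parts partition the input and the split is reproducible
#' given the seed.
#'
#' @param table An `obs_table`.
#' @param fraction Holdout fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @param scheme `"random"` (stratified) or `"last_years"` (holds out
#'   the most recent `fraction` of each age group's reference years).
#' @return List with `train` and `holdout` (both `obs_table`).
#' @export
holdout_split <- function(table, fraction = 0.20, seed = 1,
                          scheme = c("random", "last_years")) {
  stopifnot(inherits(table, "obs_table"))
  scheme <- match.arg(scheme)
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1)
    stop_sexmort("fraction must lie in [0, 1)")
  n <- nrow(table)
  if (n == 0) stop_sexmort("observation table is empty")
  n_hold <- round(fraction * n)
  if (n_hold == 0)
    return(list(train = table, holdout = table[0, , drop = FALSE]))
  set.seed(seed)
  groups <- split(seq_len(n), table$age_group)
  if (scheme == "random") {
    raw <- vapply(groups, length, numeric(1)) * fraction
    base <- floor(raw)
    rem <- n_hold - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    hold <- unlist(lapply(seq_along(groups), function(g)
      if (base[g] > 0) sample(groups[[g]], base[g]) else integer(0)))
  } else {
    hold <- unlist(lapply(groups, function(ii) {
      k <- round(fraction * length(ii))
      if (k == 0) return(integer(0))
      ii[order(table$ref_year[ii], decreasing = TRUE)[seq_len(k)]]
    }))
  }
  hold <- sort(hold)
  keep_tab <- function(ii) {
    out <- table[ii, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- class(table)
    out
  }
  list(train = keep_tab(setdiff(seq_len(n), hold)), holdout = keep_tab(hold))
}

#' Predictive coverage report on held-out observations
#'
#' For every held-out record, builds the 90% (or `level`) posterior
#' predictive interval for the observed log sex ratio — posterior draws
#' of the country-year log ratio plus Normal observation noise with
#' variance equal to the record's sampling variance plus the (drawn or
#' fixed) squared non-sampling SD of its source — and reports the share
#' of records falling inside, with mean and median prediction errors on
#' the log-ratio scale and a per-source-type breakdown.
#'
#' @param fitted A [fit_model()] result covering every holdout cell.
#' @param holdout An `obs_table` of held-out records.
#' @param error_model Optional [error_model()] of fixed non-sampling
#'   SDs; by default the posterior draws of sigma from `fitted` are
#'   used.
#' @param level Predictive-interval level (default 0.90).
#' @param seed Seed for the predictive noise draws.
#' @param holdout_fraction The fraction that was held out, recorded in
#'   the report (not recomputable from the holdout alone).
#' @return An object of class `validation_report`: list with
#'   `holdout_fraction`, `n_holdout`, `coverage`, `mean_error`,
#'   `median_error`, and `by_source` (data frame).
#' @export
coverage_report <- function(fitted, holdout, error_model = NULL,
                            level = 0.90, seed = 1,
                            holdout_fraction = NA_real_) {
  stopifnot(inherits(fitted, "posterior_trajectories"),
            inherits(holdout, "obs_table"))
  if (nrow(holdout) == 0) stop_sexmort("holdout table is empty")
  a <- (1 - level) / 2
  set.seed(seed)
  covered <- err <- numeric(nrow(holdout))
  for (i in seq_len(nrow(holdout))) {
    rec <- holdout[i, ]
    f <- fitted$age_groups[[rec$age_group]]
    if (is.null(f)) stop_sexmort("no fit for age group ", rec$age_group)
    ci <- match(rec$country_code, f$countries)
    ti <- nearest_year_index(rec$ref_year, f$years)
    if (is.na(ci))
      stop_sexmort("holdout record outside the fitted grid: ",
                   rec$country_code)
    logS <- log(f$S[, ci, ti])
    sig <- if (!is.null(error_model)) {
      error_model$sigma_by_source[[rec$source_type]]
    } else {
      col <- paste0("sigma_", rec$source_type)
      if (col %in% names(f$hyper)) f$hyper[[col]] else 0
    }
    y_rep <- logS + rnorm(length(logS), 0,
                          sqrt(rec$log_se_sampling^2 + sig^2))
    qi <- quantile(y_rep, c(a, 1 - a), type = 7, names = FALSE)
    y <- log(rec$sex_ratio_obs)
    covered[i] <- (y >= qi[1]) && (y <= qi[2])
    err[i] <- y - median(logS)
  }
  by_source <- do.call(rbind, lapply(split(seq_len(nrow(holdout)),
                                           holdout$source_type),
                                     function(ii)
    data.frame(source_type = holdout$source_type[ii[1]], n = length(ii),
               coverage = mean(covered[ii]), mean_error = mean(err[ii]),
               stringsAsFactors = FALSE)))
  rownames(by_source) <- NULL
  structure(list(holdout_fraction = holdout_fraction,
                 n_holdout = nrow(holdout),
                 coverage = mean(covered),
                 mean_error = mean(err),
                 median_error = median(err),
                 by_source = by_source),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: %d held-out records, coverage %.3f, ",
              x$n_holdout, x$coverage),
      sprintf("mean log-ratio error %+.4f\n", x$mean_error))
  print(x$by_source)
  invisible(x)
}
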