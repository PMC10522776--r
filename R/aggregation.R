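## Regional and global aggregation: sex-specific death counts, regional
## sex-specific rates, male shares of deaths, and the additive crisis-deaths
## adjustment hook.

#' Regional sex-specific rates from death shares
#'
#' Applies the proportions of sex-specific deaths within a region to
#' the region's total mortality rate:
#' `q_female = q_total * (death share female) / c_female` and
#' analogously for males, where `(c_female, c_male)` are the exposure
#' shares.  The conservation identity
#' `c_female * q_female + c_male * q_male = q_total` holds exactly.
#'
#' @param deaths_female,deaths_male Regional death counts (nonnegative,
#'   positive total).
#' @param q_total_region Regional total probability of dying, in (0, 1).
#' @param exposure_shares Numeric `c(female, male)` exposure shares in
#'   (0, 1) summing to 1.
#' @return List with `q_female_region`, `q_male_region`.
#' @export
aggregate_region_rates <- function(deaths_female, deaths_male,
                                   q_total_region, exposure_shares) {
  total <- deaths_female + deaths_male
  if (any(deaths_female < 0) || any(deaths_male < 0) || any(total <= 0))
    stop_sexmort("deaths must be >= 0 with a positive total")
  if (length(exposure_shares) != 2 ||
      abs(sum(exposure_shares) - 1) > 1e-12 ||
      any(exposure_shares <= 0) || any(exposure_shares >= 1))
    stop_sexmort("exposure_shares must be two shares in (0, 1) summing to 1")
  if (any(q_total_region <= 0) || any(q_total_region >= 1))
    stop_sexmort("q_total_region must lie in (0, 1)")
  share_f <- deaths_female / total
  list(q_female_region = q_total_region * share_f / exposure_shares[1],
       q_male_region = q_total_region * (1 - share_f) / exposure_shares[2])
}

#' Male share of deaths
#'
#' Percentage of deaths that are male across the supplied age groups:
#' `100 * sum(deaths_male) / (sum(deaths_male) + sum(deaths_female))`.
#'
#' @param deaths_female,deaths_male Death counts per age group.
#' @return Male share as a percentage.
#' @export
male_share_of_deaths <- function(deaths_female, deaths_male) {
  if (!is_count(deaths_female) || !is_count(deaths_male))
    stop_sexmort("deaths must be nonnegative counts")
  tot <- sum(deaths_female) + sum(deaths_male)
  if (tot <= 0) stop_sexmort("total deaths must be positive")
  100 * sum(deaths_male) / tot
}

#' Additive crisis-deaths adjustment
#'
#' Adds user-supplied sex-specific crisis death counts to the modelled
#' counts for the matching (country, year, age group) rows; rows
#' without a crisis entry are unchanged.  When the crisis input is
#' `NULL` the counts are returned as-is.
#'
#' @param deaths Data frame `country_code, year, age_group,
#'   deaths_male, deaths_female`.
#' @param crisis_deaths Optional data frame with the same keys and
#'   `crisis_deaths_male`, `crisis_deaths_female` (nonnegative).
#' @return `deaths` with adjusted counts.
#' @export
apply_crisis_adjustment <- function(deaths, crisis_deaths = NULL) {
  if (is.null(crisis_deaths)) return(deaths)
  if (any(crisis_deaths$crisis_deaths_male < 0) ||
      any(crisis_deaths$crisis_deaths_female < 0))
    stop_sexmort("crisis death counts must be >= 0")
  key <- function(d) paste(d$country_code, d$year, d$age_group, sep = "\r")
  i <- match(key(crisis_deaths), key(deaths))
  if (anyNA(i))
    stop_sexmort("crisis rows refer to country-year-age cells absent ",
                 "from the modelled deaths")
  deaths$deaths_male[i] <- deaths$deaths_male[i] +
    crisis_deaths$crisis_deaths_male
  deaths$deaths_female[i] <- deaths$deaths_female[i] +
    crisis_deaths$crisis_deaths_female
  deaths
}

#' Load a region map
#'
#' @param path CSV with columns `country_code, region`.
#' @return Data frame of class `region_map`.
#' @export
load_region_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("country_code", "region") %in% names(df)))
    stop_sexmort("region map needs columns country_code, region")
  if (anyDuplicated(df$country_code))
    stop_sexmort("duplicate country_code in region map")
  structure(df, class = c("region_map", "data.frame"))
}

#' Aggregate country death-count draws to regions
#'
#' Draw-wise sums of member-country death counts per (region, year,
#' age group), preserving within-draw coherence; intervals are
#' summarised afterwards with [summarize_ui()].  Every country in the
#' input must be mapped to a region.
#'
#' @param country_deaths Long data frame `country_code, year,
#'   age_group, draw, deaths_female, deaths_male`.
#' @param region_map Data frame `country_code, region`.
#' @return Long data frame `region, year, age_group, draw,
#'   deaths_female, deaths_male, male_share` (share in percent).
#' @export
aggregate_deaths_by_region <- function(country_deaths, region_map) {
  region <- region_map$region[match(country_deaths$country_code,
                                    region_map$country_code)]
  if (anyNA(region))
    stop_sexmort("unmapped country code(s): ",
                 paste(unique(country_deaths$country_code[is.na(region)]),
                       collapse = ", "))
  out <- aggregate(
    country_deaths[c("deaths_female", "deaths_male")],
    by = list(region = region, year = country_deaths$year,
              age_group = country_deaths$age_group,
              draw = country_deaths$draw),
    FUN = sum)
  out$male_share <- 100 * out$deaths_male /
    (out$deaths_male + out$deaths_female)
  out[order(out$region, out$year, out$age_group, out$draw), ]
}
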