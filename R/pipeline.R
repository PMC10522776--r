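## Pipeline orchestration: simulate -> fit -> derive -> aggregate -> validate,
## driven by one YAML configuration, with a run manifest per invocation.

PIPELINE_STAGES <- c("simulate", "fit", "derive", "aggregate", "validate")

# Per-stage seeds derive from the master seed by a fixed rule so each
# stage is reproducible in isolation.
stage_seed <- function(master_seed, stage) {
  (as.integer(master_seed) * 101L +
     match(stage, PIPELINE_STAGES) * 1009L) %% 2147483647L
}

read_pipeline_config <- function(config_path) {
  if (!file.exists(config_path))
    stop_sexmort("config file not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  cfg$seed <- cfg$seed %||% 1L
  cfg$simulation <- cfg$simulation %||% list()
  cfg$model <- cfg$model %||% list()
  cfg$validation <- cfg$validation %||% list()
  cfg
}

pipeline_sim_config <- function(cfg, seed) {
  s <- cfg$simulation
  yrs <- s$years %||% c(1990, 2021)
  do.call(sim_config, c(
    list(seed = seed, years = yrs[1]:yrs[2]),
    s[intersect(names(s), setdiff(names(formals(sim_config)),
                                  c("seed", "years", "curve_truth")))]))
}

pipeline_model_config <- function(cfg, seed) {
  m <- cfg$model
  yrs <- cfg$simulation$years %||% c(1990, 2021)
  do.call(model_config, c(
    list(seed = seed, years = yrs[1]:yrs[2]),
    m[intersect(names(m), setdiff(names(formals(model_config)),
                                  c("seed", "years", "fixed")))]))
}

#' Run the estimation pipeline
#'
#' Orchestrates the requested stages in dependency order under one
#' output directory: `simulate` writes synthetic inputs with a
#' ground-truth manifest; `fit` estimates the model from the
#' observation and totals CSVs; `derive` computes sex-specific
#' mortality, excess female mortality, and outlier flags; `aggregate`
#' sums sex-specific deaths to regions; `validate` refits on an 80%
#' training split and reports predictive coverage.  A JSON run manifest
#' (config hash, seeds, input checksums, timings, diagnostics) is
#' written whether the run succeeds or fails.
#'
#' @param config_path Path to the YAML configuration.
#' @param stages Subset of `c("simulate", "fit", "derive", "aggregate",
#'   "validate")`.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master seed overriding the config.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config_path, stages = PIPELINE_STAGES, out_dir,
                         seed = NULL) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop_sexmort("unknown stage name(s): ", paste(unknown, collapse = ", "))
  cfg <- read_pipeline_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]

  manifest <- list(config_path = normalizePath(config_path),
                   config_hash = unname(tools::md5sum(config_path)),
                   master_seed = cfg$seed,
                   stage_seeds = sapply(stages, function(s)
                     stage_seed(cfg$seed, s)),
                   package_version = as.character(
                     utils::packageVersion("sexmort")),
                   stages = stages, status = "running", timings = list(),
                   diagnostics = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  on.exit(write_manifest())

  paths <- list(
    observations = file.path(out_dir, "observations.csv"),
    totals = file.path(out_dir, "totals.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    regions = file.path(out_dir, "regions.csv"),
    fit = file.path(out_dir, "fit.rds"),
    fit_summary = file.path(out_dir, "sex_ratio_summary.csv"),
    excess = file.path(out_dir, "excess_summary.csv"),
    region_summary = file.path(out_dir, "region_summary.csv"),
    validation = file.path(out_dir, "validation_report.csv"))

  need <- function(path, producer) {
    if (!file.exists(path))
      stop_sexmort("missing upstream artifact ", path,
                   " (run the '", producer, "' stage first)")
    path
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  status <- tryCatch({
    if ("simulate" %in% stages) timed("simulate", {
      scfg <- pipeline_sim_config(cfg, stage_seed(cfg$seed, "simulate"))
      totals <- simulate_total_mortality(scfg)
      truth <- simulate_truth(totals, scfg)
      obs <- simulate_observations(truth, scfg)
      write_simulation(truth, obs, out_dir)
    })
    if (any(c("fit", "derive", "aggregate", "validate") %in% stages)) {
      obs <- load_observations(need(paths$observations, "simulate"))
      totals <- read.csv(need(paths$totals, "simulate"),
                         stringsAsFactors = FALSE)
      totals$age_group <- as.character(totals$age_group)
    }
    if ("fit" %in% stages) timed("fit", {
      mcfg <- pipeline_model_config(cfg, stage_seed(cfg$seed, "fit"))
      obs <- filter_extremes(obs)$table
      fit <- fit_model(obs, totals, mcfg)
      saveRDS(fit, paths$fit)
      write.csv(posterior_summary(fit), paths$fit_summary, row.names = FALSE)
      manifest$diagnostics$rhat <- as.list(round(fit$diagnostics$rhat, 4))
      manifest$diagnostics$convergence <- fit$diagnostics$status
    })
    if (any(c("derive", "aggregate") %in% stages))
      fit <- readRDS(need(paths$fit, "fit"))
    if ("derive" %in% stages) timed("derive", {
      weights <- default_weights(totals, srb = cfg$srb %||% 1.05)
      fitx <- trajectories_to_sex_specific(fit, totals, weights)
      excess <- derive_excess(fitx, weights)
      write.csv(excess, paths$excess, row.names = FALSE)
    })
    if ("aggregate" %in% stages) timed("aggregate", {
      weights <- default_weights(totals, srb = cfg$srb %||% 1.05)
      fitx <- trajectories_to_sex_specific(fit, totals, weights)
      cohort <- read.csv(need(paths$cohort, "simulate"),
                         stringsAsFactors = FALSE)
      region_map <- load_region_map(need(paths$regions, "simulate"))
      cd <- country_death_draws(fitx, weights, cohort,
                                srb = cfg$srb %||% 1.05)
      reg <- aggregate_deaths_by_region(cd, region_map)
      reg_sum <- summarize_region_draws(reg)
      write.csv(reg_sum, paths$region_summary, row.names = FALSE)
    })
    if ("validate" %in% stages) timed("validate", {
      vcfg <- cfg$validation
      frac <- vcfg$fraction %||% 0.2
      sp <- holdout_split(obs, fraction = frac,
                          seed = stage_seed(cfg$seed, "validate"))
      mcfg <- pipeline_model_config(cfg, stage_seed(cfg$seed, "validate"))
      refit <- fit_model(sp$train, totals, mcfg)
      rep <- coverage_report(refit, sp$holdout,
                             seed = stage_seed(cfg$seed, "validate"),
                             holdout_fraction = frac)
      write.csv(data.frame(holdout_fraction = frac,
                           n_holdout = rep$n_holdout,
                           coverage = rep$coverage,
                           mean_error = rep$mean_error,
                           median_error = rep$median_error),
                paths$validation, row.names = FALSE)
      manifest$diagnostics$validation_coverage <- rep$coverage
    })
    "ok"
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    stop(e)
  })
  manifest$status <- status
  write_manifest()
  on.exit()
  invisible(paths)
}

# Country-level death-count draws from sex-specific mortality draws and
# cohort sizes (person-years entering the age group, split by SRB).
country_death_draws <- function(fitx, weights, cohort, srb = 1.05) {
  out <- list()
  for (ag in names(fitx$age_groups)) {
    f <- fitx$age_groups[[ag]]
    if (is.null(f$q_male))
      stop_sexmort("run trajectories_to_sex_specific before aggregating")
    n_draws <- dim(f$S)[1]
    coh <- cohort$cohort[match(f$countries, cohort$country_code)]
    if (anyNA(coh)) stop_sexmort("missing cohort size for some country")
    w_m <- srb / (1 + srb)
    Cm <- matrix(coh * w_m, length(f$countries), length(f$years))
    Cf <- matrix(coh * (1 - w_m), length(f$countries), length(f$years))
    grid <- expand.grid(country_code = f$countries, year = f$years,
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(n_draws), function(d)
      data.frame(grid, age_group = ag, draw = d,
                 deaths_female = as.vector(f$q_female[d, , ] * Cf),
                 deaths_male = as.vector(f$q_male[d, , ] * Cm),
                 stringsAsFactors = FALSE))
    out[[ag]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

# Summarise regional draw-wise aggregates with 90% intervals.
summarize_region_draws <- function(reg) {
  keys <- unique(reg[c("region", "year", "age_group")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- reg$region == keys$region[i] & reg$year == keys$year[i] &
      reg$age_group == keys$age_group[i]
    sf <- summarize_ui(reg$deaths_female[sel])
    sm <- summarize_ui(reg$deaths_male[sel])
    ss <- summarize_ui(reg$male_share[sel])
    data.frame(keys[i, ],
               deaths_female = sf[["median"]],
               deaths_female_lower = sf[["lower"]],
               deaths_female_upper = sf[["upper"]],
               deaths_male = sm[["median"]],
               deaths_male_lower = sm[["lower"]],
               deaths_male_upper = sm[["upper"]],
               male_share = ss[["median"]],
               male_share_lower = ss[["lower"]],
               male_share_upper = ss[["upper"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
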