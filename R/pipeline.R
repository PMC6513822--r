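# Pipeline driver: the linear workflow simulate -> fit -> estimate ->
# validate, with each stage reading and writing delimited text so stages can
# be cached, inspected and re-run independently. A YAML run configuration
# holds the paths and options; `run_pipeline()` chains all stages.

#' Load a run configuration
#'
#' Reads a YAML key-value file and fills defaults. Recognised keys: `seed`,
#' `year`, `n_zones`, `survey_size`, `data_dir`, `output_dir`, `max_iter`,
#' `tol`, `order`, `empty_cells`.
#'
#' @param path YAML file path, or a named list of overrides.
#' @return Named list of class `run_config`.
#' @export
load_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else as.list(path)
  cfg <- list(seed = 1L, year = 2016L, n_zones = 30L, survey_size = 12000L,
              data_dir = "msim_data", output_dir = "msim_output",
              max_iter = 50L, tol = 1e-4, order = .CONSTRAINT_VARS,
              empty_cells = "drop")
  cfg[names(user)] <- user
  if (cfg$year < 2008 || cfg$year > 2016) {
    stop("year must lie in 2008-2016 (shipped price-table vintages)")
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Stage 1: simulate a synthetic world to disk
#'
#' Builds a [world_config()] from the run configuration, generates the
#' population, survey and constraint inputs, and writes the full file set to
#' `data_dir`.
#'
#' @param config A `run_config` (or path/list accepted by
#'   [load_run_config()]).
#' @return The `world_config` used, invisibly.
#' @export
run_simulate <- function(config) {
  config <- load_run_config(config)
  wc <- world_config(n_zones = config$n_zones,
                     survey_size = config$survey_size,
                     seed = config$seed, year = config$year,
                     rrcpl = select_vintage(config$year))
  world <- generate_population(wc)
  survey <- sample_survey(world$population, wc)
  write_world(world, survey, wc, config$data_dir)
  message("simulated world written to ", config$data_dir)
  invisible(wc)
}

#' Stage 2: prepare, constrain and fit
#'
#' Reads the simulated (or externally formatted) inputs from `data_dir`,
#' restricts the microdata to the study calendar year, splits adults and
#' children, scales every constraint to the baseline, builds the income
#' constraint, and fits the adult IPF model and the closed-form child model.
#' Weights, diagnostics and the per-zone internal-validation correlations are
#' written to `output_dir`.
#'
#' @param config A `run_config`.
#' @param allow_nonconverged Keep going (with a warning) if the adult model
#'   does not converge; otherwise an error.
#' @return List with `adult` and `child` `msim_fit` objects, invisibly.
#' @export
run_fit <- function(config, allow_nonconverged = FALSE) {
  config <- load_run_config(config)
  dd <- config$data_dir
  h <- config_hash(config)
  micro <- read_msim_csv(file.path(dd, "microdata.csv"))
  micro <- filter_calendar_year(micro, config$year)
  micro <- validate_microdata(micro)
  pools <- split_adult_child(micro)

  cons <- list()
  for (v in c("age_sex", "household_type", "ethnicity", "student",
              "unemployment")) {
    cons[[v]] <- df_to_constraint(
      read_msim_csv(file.path(dd, paste0("constraint_", v, ".csv"))), v)
  }
  bl <- build_baseline(cons$age_sex)
  for (v in setdiff(names(cons), "age_sex")) {
    cons[[v]] <- scale_constraint(cons[[v]], bl$baseline)
  }
  inc_df <- read_msim_csv(file.path(dd, "income.csv"))
  income <- build_income_constraint(
    inc_df[c("zone_code", paste0("p", seq(10, 80, 10)))],
    inc_df[c("zone_code", "employees", "self_employed", "other")],
    bl$baseline)
  manifest <- read_msim_csv(file.path(dd, "manifest.csv"))

  fit <- ipf_fit(pools$adults, cons, bl$baseline, income, manifest,
                 order = config$order, max_iter = config$max_iter,
                 tol = config$tol, empty_cells = config$empty_cells)
  if (!fit$diagnostics$converged) {
    msg <- sprintf("adult model did not converge in %d sweeps",
                   fit$diagnostics$iterations)
    if (allow_nonconverged) warning(msg) else stop(msg)
  }
  child_con <- df_to_constraint(
    read_msim_csv(file.path(dd, "constraint_child_age_sex.csv")), "age_sex")
  child_bl <- build_baseline(child_con)
  child_fit <- fit_child_model(pools$children, child_bl$constraint)

  od <- config$output_dir
  write_weights(fit, file.path(od, "weights_adult.csv"), config$seed, h)
  write_weights(child_fit, file.path(od, "weights_child.csv"), config$seed, h)
  iv <- internal_validation(fit)
  write_msim_csv(iv, file.path(od, "internal_validation.csv"), config$seed, h)
  write_msim_csv(data.frame(sweep = seq_len(nrow(fit$diagnostics$tae)),
                            fit$diagnostics$tae, check.names = FALSE),
                 file.path(od, "tae.csv"), config$seed, h)
  message("fit written to ", od, " (", fit$diagnostics$iterations,
          " sweeps, min zone correlation ",
          format(min(iv$r, na.rm = TRUE), digits = 6), ")")
  invisible(list(adult = fit, child = child_fit))
}

#' Stage 3: zone expenditure estimates
#'
#' Combines cached weights with the price-adjusted diary into zone-level
#' average weekly expenditure per person, appends the standard aggregate
#' categories, and writes the long-format estimates CSV.
#'
#' @param config A `run_config`.
#' @return The `expenditure_estimate` data frame, invisibly.
#' @export
run_estimate <- function(config) {
  config <- load_run_config(config)
  dd <- config$data_dir; od <- config$output_dir
  h <- config_hash(config)
  W <- read_weights(file.path(od, "weights_adult.csv"))
  micro <- read_msim_csv(file.path(dd, "microdata.csv"))
  diary <- read_msim_csv(file.path(dd, "diary.csv"))
  zones <- read_msim_csv(file.path(dd, "zones.csv"))
  region_of_zone <- stats::setNames(zones$region, zones$zone_code)
  rr <- select_vintage(config$year)

  totals <- zone_expenditure(W, diary, micro, region_of_zone, rr)
  adult_pop <- stats::setNames(zones$adult_population, zones$zone_code)
  child_pop <- stats::setNames(zones$child_population, zones$zone_code)
  est <- merge_per_capita(totals, NULL, adult_pop, child_pop)
  agg <- aggregate_categories(est, standard_aggregates())
  out <- rbind(est, agg)
  cat_tab <- read_msim_csv(file.path(dd, "catalogue.csv"))
  out$description <- cat_tab$description[match(out$coicop, cat_tab$coicop)]
  out$year <- config$year
  write_msim_csv(out[c("year", "zone_code", "coicop", "description",
                       "mean_weekly_expenditure_gbp")],
                 file.path(od, "estimates.csv"), config$seed, h)
  message("estimates written to ", file.path(od, "estimates.csv"))
  invisible(out)
}

#' Stage 4: validation report
#'
#' External validation of cached estimates: regional aggregates against the
#' survey means (within 1.96 standard errors), and Spearman rank correlation
#' of the standard aggregate categories against the deprivation ranking.
#'
#' @param config A `run_config`.
#' @return List with `regional` and `deprivation` tables, invisibly.
#' @export
run_validate <- function(config) {
  config <- load_run_config(config)
  dd <- config$data_dir; od <- config$output_dir
  h <- config_hash(config)
  est <- read_msim_csv(file.path(od, "estimates.csv"))
  class(est) <- c("expenditure_estimate", "data.frame")
  zones <- read_msim_csv(file.path(dd, "zones.csv"))
  pop <- stats::setNames(zones$adult_population + zones$child_population,
                         zones$zone_code)
  region_of_zone <- stats::setNames(zones$region, zones$zone_code)
  survey <- read_msim_csv(file.path(dd, "survey_regional_stats.csv"))
  leaf <- est[!est$coicop %in% names(standard_aggregates()), , drop = FALSE]
  reg <- regional_comparison(leaf, pop, region_of_zone, survey)

  ranks <- read_msim_csv(file.path(dd, "deprivation_rank.csv"))
  rk <- stats::setNames(ranks$rank, ranks$zone_code)
  dep <- do.call(rbind, lapply(names(standard_aggregates()), function(g) {
    sub <- est[est$coicop == g, , drop = FALSE]
    x <- stats::setNames(sub$mean_weekly_expenditure_gbp, sub$zone_code)
    rc <- rank_correlation(x, rk)
    data.frame(category = g, rho = rc$rho, p_value = rc$p_value, n = rc$n,
               stringsAsFactors = FALSE)
  }))
  write_msim_csv(reg, file.path(od, "regional_comparison.csv"), config$seed, h)
  write_msim_csv(dep, file.path(od, "deprivation_correlation.csv"),
                 config$seed, h)
  message("validation report written to ", od)
  invisible(list(regional = reg, deprivation = dep))
}

#' Audit constraint availability
#'
#' @param config A `run_config`.
#' @return The audit table (zones with each constraint available).
#' @export
run_audit <- function(config) {
  config <- load_run_config(config)
  manifest <- read_msim_csv(file.path(config$data_dir, "manifest.csv"))
  audit_constraints(manifest)
}

#' Run the full pipeline
#'
#' `run_simulate()` then [run_fit()], [run_estimate()] and [run_validate()],
#' returning the validation tables.
#'
#' @param config A `run_config` (or path/list).
#' @param simulate Generate the synthetic inputs first (disable when
#'   `data_dir` already holds formatted inputs).
#' @return Output of [run_validate()].
#' @export
run_pipeline <- function(config, simulate = TRUE) {
  config <- load_run_config(config)
  if (simulate) run_simulate(config)
  run_fit(config)
  run_estimate(config)
  run_validate(config)
}
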