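# Delimited-text plumbing. Every output file carries a header comment with
# the package version, the run seed and a hash of the configuration, so a
# result file can always be traced to the run that made it.

.str_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  # polynomial rolling hash mod a Mersenne prime; stays inside exact-double
  # integer range
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a data frame as a stamped CSV
#'
#' Writes UTF-8 CSV with a leading `#` comment line recording the package
#' version, seed and configuration hash.
#'
#' @param df Data frame.
#' @param path Output path (directories created as needed).
#' @param seed Seed to record.
#' @param config_hash Configuration hash to record (see [config_hash()]).
#' @export
write_msim_csv <- function(df, path, seed = NA, config_hash = "") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# microspend %s; seed=%s; config=%s",
                     as.character(utils::packageVersion("microspend")),
                     seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a stamped CSV
#'
#' @param path CSV path; `#` comment lines are skipped.
#' @return Data frame.
#' @export
read_msim_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Hash a run configuration
#'
#' Deterministic 32-bit FNV-1a hash of the YAML serialisation of a config
#' list, recorded in every output header for provenance.
#'
#' @param config A list.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("rrcpl", "attribute_distributions"))]
  .str_hash(yaml::as.yaml(cfg[order(names(cfg))]))
}

constraint_to_df <- function(tab) {
  data.frame(zone_code = rownames(tab), as.data.frame(unclass(tab)),
             check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

df_to_constraint <- function(df, variable) constraint_table(df, variable)

#' Write a synthetic world to disk
#'
#' Emits the full file set of a simulated study into `dir`: formatted
#' microdata and diary CSVs, one raw constraint CSV per variable, the income
#' boundary/employment CSV in the standard percentile layout, the child
#' age-sex constraint, the availability manifest, the zone-to-region map,
#' the ground-truth zone expenditure, the deprivation ranking and the
#' regional survey statistics.
#'
#' @param world Result of [generate_population()].
#' @param survey Result of [sample_survey()].
#' @param config The `world_config`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, survey, config, dir) {
  h <- config_hash(config)
  s <- config$seed
  w <- function(df, name) write_msim_csv(df, file.path(dir, name), s, h)
  tabs <- world$ground_truth$true_population_tables

  w(survey$microdata, "microdata.csv")
  w(survey$diary, "diary.csv")
  for (v in names(tabs$adult)) {
    w(constraint_to_df(tabs$adult[[v]]), paste0("constraint_", v, ".csv"))
  }
  inc <- merge(tabs$income$boundaries, tabs$income$employment, by = "zone_code")
  w(inc, "income.csv")
  w(constraint_to_df(tabs$child), "constraint_child_age_sex.csv")
  manifest <- data.frame(zone_code = config$zones,
                         age_sex = TRUE, household_type = TRUE,
                         ethnicity = TRUE, student = TRUE,
                         unemployment = TRUE, income = TRUE,
                         stringsAsFactors = FALSE)
  w(manifest, "manifest.csv")
  w(data.frame(zone_code = names(config$region_of_zone),
               region = unname(config$region_of_zone),
               adult_population = unname(config$adult_populations),
               child_population = unname(config$child_populations),
               stringsAsFactors = FALSE), "zones.csv")
  truth <- world$ground_truth$true_zone_expenditure
  w(data.frame(zone_code = rep(rownames(truth), ncol(truth)),
               coicop = rep(colnames(truth), each = nrow(truth)),
               mean_weekly_expenditure_gbp = as.vector(truth),
               stringsAsFactors = FALSE), "ground_truth.csv")
  w(data.frame(zone_code = names(world$ground_truth$deprivation_rank),
               rank = unname(world$ground_truth$deprivation_rank),
               stringsAsFactors = FALSE), "deprivation_rank.csv")
  w(survey_regional_stats(survey, config), "survey_regional_stats.csv")
  w(config$catalogue, "catalogue.csv")
  invisible(dir)
}

#' Write fitted weights as a long CSV
#'
#' @param fit An `msim_fit`.
#' @param path Output path.
#' @param seed,config_hash Provenance stamps.
#' @export
write_weights <- function(fit, path, seed = NA, config_hash = "") {
  W <- fit$weights
  df <- data.frame(individual_id = rep(rownames(W), ncol(W)),
                   zone_code = rep(colnames(W), each = nrow(W)),
                   weight = as.vector(W), stringsAsFactors = FALSE)
  write_msim_csv(df, path, seed, config_hash)
}

#' Read a long-form weight CSV back into a matrix
#'
#' @param path Path written by [write_weights()].
#' @return Individuals x zones matrix.
#' @export
read_weights <- function(path) {
  df <- read_msim_csv(path)
  ids <- unique(df$individual_id)
  zones <- unique(df$zone_code)
  W <- matrix(0, length(ids), length(zones), dimnames = list(ids, zones))
  W[cbind(match(df$individual_id, ids), match(df$zone_code, zones))] <- df$weight
  W
}
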