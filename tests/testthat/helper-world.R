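# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

# Full-size synthetic study: 30 zones, 12,000-person survey, all six
# constraints, fitted adult model and per-capita estimates.
full_world <- function() {
  if (!is.null(.cache$full)) return(.cache$full)
  wc <- world_config(n_zones = 30, survey_size = 12000, seed = 42)
  world <- generate_population(wc)
  survey <- sample_survey(world$population, wc)
  tabs <- world$ground_truth$true_population_tables
  bl <- build_baseline(tabs$adult$age_sex)
  cons <- tabs$adult
  for (v in setdiff(names(cons), "age_sex")) {
    cons[[v]] <- scale_constraint(cons[[v]], bl$baseline)
  }
  cons$age_sex <- bl$constraint
  inc <- build_income_constraint(tabs$income$boundaries,
                                 tabs$income$employment, bl$baseline)
  pools <- split_adult_child(validate_microdata(survey$microdata))
  fit <- ipf_fit(pools$adults, cons, bl$baseline, inc)
  child_bl <- build_baseline(tabs$child)
  child_fit <- fit_child_model(pools$children, child_bl$constraint)
  totals <- zone_expenditure(fit, survey$diary, survey$microdata,
                             wc$region_of_zone, wc$rrcpl)
  est <- merge_per_capita(totals, NULL, tabs$baseline$adult,
                          tabs$baseline$child)
  agg <- aggregate_categories(est, standard_aggregates())
  .cache$full <- list(wc = wc, world = world, survey = survey, tabs = tabs,
                      bl = bl, cons = cons, inc = inc, pools = pools,
                      fit = fit, child_fit = child_fit, totals = totals,
                      est = est, agg = agg)
  .cache$full
}

# A four-person, one-zone, two-constraint toy whose IPF solution is a 2x2
# contingency table.
toy_2x2 <- function(age_targets = c(F_25_34 = 60, M_25_34 = 40),
                    hh_targets = c(`25_34_dep_n` = 70, `55_64_sph` = 30)) {
  md <- data.frame(
    id = c("1.1", "1.2", "2.1", "2.2"), region = "Wales",
    age_sex = c("F_25_34", "F_25_34", "M_25_34", "M_25_34"),
    ethnicity = "white", student = "not-student",
    unemployed = "not-unemployed", gross_weekly_wage = 400,
    employment_type = "Employee",
    household_type = c("25_34_dep_n", "55_64_sph", "25_34_dep_n", "55_64_sph"),
    stringsAsFactors = FALSE
  )
  cons <- list(
    age_sex = constraint_table(
      matrix(age_targets, 1, 2, dimnames = list("Z1", names(age_targets))),
      "age_sex"),
    household_type = constraint_table(
      matrix(hh_targets, 1, 2, dimnames = list("Z1", names(hh_targets))),
      "household_type")
  )
  list(md = md, cons = cons, baseline = c(Z1 = sum(age_targets)))
}

# independent oracle: classical matrix scaling of a 2x2 array
scale_2x2 <- function(seed_mat, row_targets, col_targets, iters = 1000) {
  m <- seed_mat
  for (i in seq_len(iters)) {
    m <- m * (row_targets / rowSums(m))
    m <- t(t(m) * (col_targets / colSums(m)))
  }
  m
}

# worked-example fixture paths
lad_example <- function(name) {
  system.file("extdata", "lad_example_2008", name, package = "microspend",
              mustWork = TRUE)
}
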