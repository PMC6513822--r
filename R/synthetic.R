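# Synthetic-world generator.
#
# Stands in for the licensed survey and census sources: simulates a true
# population across zones with zone-varying socio-demographics, derives the
# per-zone marginal constraint tables from it exactly, and draws a survey
# (microdata + expenditure diary) whose spending depends on the attributes
# through a log-linear model with lognormal noise. Because the truth is
# known, every downstream stage (scaling, IPF, price adjustment, estimation,
# validation) can be tested end to end, including parameter recovery.

#' Default commodity catalogue for the synthetic world
#'
#' A small synthetic COICOP catalogue spanning the three price divisions:
#' food and non-alcoholic drink (division 1), alcohol and tobacco (division
#' 2) and catering (division 11). `baseline_gbp` is the weekly spend of a
#' reference adult, `sdlog` the lognormal noise scale on the log of spend,
#' and `participation` the probability that an adult records any purchase in
#' the category in a week (zero records are omitted from the diary).
#'
#' @return Data frame `coicop`, `description`, `baseline_gbp`, `sdlog`,
#'   `participation`.
#' @export
synthetic_catalogue <- function() {
  data.frame(
    coicop = c("1.1.1.1.1", "1.1.1.4.1", "1.1.2.1.1", "1.1.2.5.1",
               "1.1.4.1.1", "1.1.6.1.1", "1.1.6.2.1", "1.1.7.1.1",
               "1.2.1.1.1", "1.2.2.2.1", "2.1.1.1.1", "2.1.3.1.1",
               "2.2.1.1.1", "11.1.1.1.1", "11.1.1.2.1"),
    description = c("Bread", "Cakes and puddings", "Beef (fresh)",
                    "Bacon and ham", "Milk (whole)", "Apples (fresh)",
                    "Bananas (fresh)", "Vegetables (fresh)", "Coffee",
                    "Soft drinks", "Spirits", "Beer and lager", "Cigarettes",
                    "Restaurant and cafe meals", "Take-away meals"),
    baseline_gbp = c(2.0, 1.2, 2.6, 1.4, 1.6, 1.0, 0.7, 1.8, 1.1, 1.5,
                     1.7, 2.4, 3.2, 5.5, 2.8),
    sdlog = c(0.45, 0.50, 0.55, 0.50, 0.40, 0.45, 0.40, 0.50, 0.50, 0.55,
              0.70, 0.70, 0.60, 0.70, 0.65),
    participation = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.55, 0.65, 0.28,
                      0.85, 0.80),
    stringsAsFactors = FALSE
  )
}

#' Default attribute effects on log weekly spend
#'
#' Additive effects on the log of expected weekly spend, keyed by microdata
#' column and a regular expression matched against the category label
#' (anchor it unless a substring match is intended). The default effects encode the stylised
#' deprivation gradients used throughout the tests: unemployment raises
#' tobacco spend and depresses food — especially fruit and vegetables — and
#' eating out; students favour beer and take-aways; older adults eat out and
#' smoke less; households with dependent children buy more staples.
#'
#' @return Data frame `variable`, `label`, `coicop`, `effect`.
#' @export
synthetic_effects <- function() {
  e <- function(variable, label, codes, effects) {
    data.frame(variable = variable, label = label, coicop = codes,
               effect = effects, stringsAsFactors = FALSE)
  }
  fruitveg <- c("1.1.6.1.1", "1.1.6.2.1", "1.1.7.1.1")
  rbind(
    e("unemployed", "^unemployed$",
      c("1.1.1.1.1", "1.1.1.4.1", "1.1.2.1.1", "1.1.2.5.1", fruitveg,
        "1.2.1.1.1", "1.2.2.2.1", "2.1.1.1.1", "2.1.3.1.1", "2.2.1.1.1",
        "11.1.1.1.1", "11.1.1.2.1"),
      c(0.05, 0.10, -0.35, -0.10, -0.55, -0.50, -0.55,
        -0.20, 0.15, 0.10, 0.15, 0.85, -0.70, -0.20)),
    e("employment_type", "^Other$",
      c("1.1.2.1.1", fruitveg, "2.1.3.1.1", "2.2.1.1.1", "11.1.1.1.1"),
      c(-0.15, -0.15, -0.15, -0.15, -0.15, 0.25, -0.35)),
    e("student", "^student$",
      c("1.1.2.1.1", "2.1.3.1.1", "2.2.1.1.1", "11.1.1.1.1", "11.1.1.2.1"),
      c(-0.20, 0.30, -0.25, 0.10, 0.35)),
    e("age_sex", "^(F|M)_(65_74|75_pl)$",
      c("1.1.6.1.1", "1.1.7.1.1", "2.2.1.1.1", "11.1.1.1.1", "11.1.1.2.1"),
      c(0.25, 0.20, -0.45, -0.40, -0.60)),
    e("age_sex", "^(F|M)_16_24$",
      c("1.2.2.2.1", "2.1.1.1.1", "11.1.1.2.1"),
      c(0.20, 0.15, 0.30)),
    e("household_type", "dep_y",
      c("1.1.1.1.1", "1.1.4.1.1", "1.2.2.2.1", "2.1.1.1.1", "2.2.1.1.1",
        "11.1.1.1.1"),
      c(0.20, 0.30, 0.25, -0.20, -0.15, -0.25))
  )
}

#' Configure a synthetic world
#'
#' Fixes every condition of the simulated study: the zones with their
#' populations and regions, the per-zone categorical attribute
#' distributions, the wage model, the expenditure model (catalogue +
#' effects + noise) and the survey design. Zones sit on a deprivation axis
#' `d` in [0, 1] (higher = more deprived) that drives unemployment, wages,
#' age structure and household composition, and a second "diversity" axis
#' that drives ethnicity and student shares — so constraints genuinely vary
#' by zone and a deprivation-linked expenditure gradient exists to recover.
#'
#' @param n_zones Number of zones.
#' @param survey_size Individuals sampled into the survey (adults and
#'   children together); must be at least 10 times the number of distinct
#'   attribute categories so the sampling pool covers every cell.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param year Study year stamped on survey records.
#' @param adult_populations,child_populations Optional per-zone population
#'   overrides.
#' @param catalogue,effects Expenditure model overrides (see
#'   [synthetic_catalogue()], [synthetic_effects()]).
#' @param rrcpl `rrcpl` table whose regional price levels are baked into the
#'   generated spend (the synthetic world has real regional price
#'   differences, so the pipeline's price adjustment is correctly
#'   specified), or `NULL` for a price-flat world.
#' @return A validated `world_config` list.
#' @export
world_config <- function(n_zones = 30, survey_size = 12000, seed = 1,
                         year = 2016,
                         adult_populations = NULL, child_populations = NULL,
                         catalogue = synthetic_catalogue(),
                         effects = synthetic_effects(),
                         rrcpl = rrcpl_table(2016)) {
  stopifnot(n_zones >= 1, survey_size >= 1)
  zones <- sprintf("E%08d", 6000000 + seq_len(n_zones))
  d <- if (n_zones == 1) 0.5 else seq(0, 1, length.out = n_zones)
  v <- ((seq_len(n_zones) * 37) %% 101) / 100
  if (is.null(adult_populations)) {
    adult_populations <- 4000 + ((seq_len(n_zones) * 977) %% 7000)
  }
  if (is.null(child_populations)) {
    child_populations <- round(0.21 * adult_populations)
  }
  names(adult_populations) <- names(child_populations) <- zones
  region_of_zone <- stats::setNames(
    rep(.GB_REGIONS, length.out = n_zones), zones)

  dist <- lapply(seq_len(n_zones), function(i) .zone_distributions(d[i], v[i]))
  names(dist) <- zones

  cfg <- structure(list(
    n_zones = n_zones, zones = zones, year = year,
    deprivation = stats::setNames(d, zones),
    diversity = stats::setNames(v, zones),
    adult_populations = adult_populations,
    child_populations = child_populations,
    region_of_zone = region_of_zone,
    attribute_distributions = dist,
    wage_model = list(
      employee = list(meanlog = log(430) + 0.35 * (0.5 - d), sdlog = 0.55),
      self_employed = list(meanlog = log(380) + 0.30 * (0.5 - d), sdlog = 0.80)
    ),
    catalogue = catalogue, effects = effects, rrcpl = rrcpl,
    survey_size = survey_size, seed = as.integer(seed)
  ), class = "world_config")
  validate_world_config(cfg)
}

# per-zone categorical probability vectors driven by the deprivation (d) and
# diversity (v) axes
.zone_distributions <- function(d, v) {
  norm <- function(p) p / sum(p)
  age_base <- c(`16_24` = 0.15, `25_34` = 0.17, `35_49` = 0.26,
                `50_64` = 0.23, `65_74` = 0.11, `75_pl` = 0.08)
  tilt <- c(1 + 0.5 * (d - 0.5), 1 + 0.2 * (d - 0.5), 1, 1,
            1 - 0.5 * (d - 0.5), 1 - 0.5 * (d - 0.5))
  age <- norm(age_base * tilt)
  age_sex <- stats::setNames(c(0.51 * age, 0.49 * age), .AGE_SEX_ADULT)

  hh_base <- c(0.06, 0.02, 0.08, 0.06, 0.02, 0.01, 0.12, 0.07, 0.07, 0.06,
               0.12, 0.04, 0.02, 0.08, 0.05, 0.06, 0.06)
  names(hh_base) <- .HOUSEHOLD_TYPE
  dep_y <- grepl("dep_y", .HOUSEHOLD_TYPE)
  hh <- norm(hh_base * ifelse(dep_y, 1 + 0.30 * (d - 0.5), 1))

  eth <- c(white = 0.94 - 0.35 * v, mixed = 0.01 + 0.02 * v,
           black = 0.02 + 0.13 * v, other = 0.03 + 0.20 * v)

  list(
    age_sex = age_sex,
    age_sex_child = stats::setNames(c(0.31, 0.18, 0.32, 0.19), .AGE_SEX_CHILD),
    ethnicity = norm(eth),
    student = stats::setNames(c(0.04 + 0.14 * v, 0.96 - 0.14 * v), .STUDENT),
    unemployment = stats::setNames(c(0.025 + 0.095 * d, 0.975 - 0.095 * d),
                                   .UNEMPLOYED),
    employment_type = norm(stats::setNames(
      c(0.62 - 0.10 * d, 0.09 + 0.03 * v, 0.29 + 0.10 * d - 0.03 * v),
      .EMPLOYMENT_TYPE)),
    household_type = hh
  )
}

#' Validate a world configuration
#'
#' Checks the configuration invariants: every per-zone categorical
#' distribution sums to 1 within 1e-9 with nonnegative probabilities, all
#' populations are positive, and the survey is at least 10 times the number
#' of distinct attribute categories (sampling-pool adequacy).
#'
#' @param config A `world_config`.
#' @return The config, invisibly-validated (errors otherwise).
#' @export
validate_world_config <- function(config) {
  if (any(config$adult_populations <= 0) || any(config$child_populations < 0)) {
    stop("zone populations must be positive")
  }
  for (z in config$zones) {
    for (var in names(config$attribute_distributions[[z]])) {
      p <- config$attribute_distributions[[z]][[var]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        stop("invalid distribution for zone ", z, ", variable ", var)
      }
    }
  }
  n_cat <- length(.AGE_SEX_ADULT) + length(.AGE_SEX_CHILD) +
    length(.ETHNICITY) + length(.STUDENT) + length(.UNEMPLOYED) +
    length(.EMPLOYMENT_TYPE) + length(.HOUSEHOLD_TYPE)
  if (config$survey_size < 10 * n_cat) {
    stop("survey_size must be >= ", 10 * n_cat,
         " (10 x distinct attribute categories)")
  }
  config
}

#' @export
print.world_config <- function(x, ...) {
  cat("Synthetic world:", x$n_zones, "zones,",
      sum(x$adult_populations), "adults +", sum(x$child_populations),
      "children; survey", x$survey_size, "; seed", x$seed, "\n")
  invisible(x)
}

#' Generate the true population and ground truth
#'
#' Simulates one record per person: zone, region, all categorical attributes,
#' gross weekly wage, and a latent expected weekly expenditure per commodity
#' category (`participation * exp(log baseline + attribute effects +
#' sdlog^2 / 2)`, times the regional price factor when the config carries an
#' RRCPL table). Deterministic given the config seed.
#'
#' @param config A `world_config`.
#' @return List with `population` (data frame; latent spend in `latent.*`
#'   columns) and `ground_truth`: `true_zone_expenditure` (zones x categories
#'   mean weekly pounds per resident, all ages), `true_population_tables`
#'   (the exact constraint tabulations, via [tabulate_constraints()]),
#'   `deprivation_rank` (1 = most deprived) and `region_of_zone`.
#' @export
generate_population <- function(config) {
  validate_world_config(config)
  set.seed(config$seed)
  zones <- config$zones
  parts <- vector("list", length(zones))
  for (zi in seq_along(zones)) {
    z <- zones[zi]
    na <- config$adult_populations[z]
    nc <- config$child_populations[z]
    dst <- config$attribute_distributions[[z]]
    samp <- function(p, n) names(p)[sample.int(length(p), n, replace = TRUE,
                                               prob = p)]
    emp <- samp(dst$employment_type, na)
    wage <- numeric(na)
    wm <- config$wage_model
    is_e <- emp == "Employee"; is_s <- emp == "Self-employed"
    wage[is_e] <- stats::rlnorm(sum(is_e), wm$employee$meanlog[zi],
                                wm$employee$sdlog)
    wage[is_s] <- stats::rlnorm(sum(is_s), wm$self_employed$meanlog[zi],
                                wm$self_employed$sdlog)
    adults <- data.frame(
      zone_code = z, region = unname(config$region_of_zone[z]),
      age_sex = samp(dst$age_sex, na),
      ethnicity = samp(dst$ethnicity, na),
      student = samp(dst$student, na),
      unemployed = samp(dst$unemployment, na),
      gross_weekly_wage = round(wage, 2),
      employment_type = emp,
      household_type = samp(dst$household_type, na),
      stringsAsFactors = FALSE
    )
    children <- if (nc > 0) data.frame(
      zone_code = z, region = unname(config$region_of_zone[z]),
      age_sex = samp(dst$age_sex_child, nc),
      ethnicity = samp(dst$ethnicity, nc),
      student = "not-student", unemployed = "not-unemployed",
      gross_weekly_wage = 0, employment_type = "Other",
      household_type = NA_character_, stringsAsFactors = FALSE
    ) else NULL
    parts[[zi]] <- rbind(adults, children)
  }
  population <- do.call(rbind, parts)
  rownames(population) <- NULL

  lat <- latent_expenditure(population, config)
  colnames(lat) <- paste0("latent.", colnames(lat))
  population <- cbind(population, lat)

  tabs <- tabulate_constraints(population)
  adult_n <- config$adult_populations[zones]
  all_n <- adult_n + config$child_populations[zones]
  zsum <- rowsum(lat, population$zone_code, reorder = TRUE)[zones, , drop = FALSE]
  truth <- zsum / all_n
  colnames(truth) <- sub("^latent\\.", "", colnames(truth))

  list(population = population,
       ground_truth = list(
         true_zone_expenditure = truth,
         true_population_tables = tabs,
         deprivation_rank = stats::setNames(
           rank(-config$deprivation, ties.method = "first"), zones),
         region_of_zone = config$region_of_zone))
}

#' Latent expected weekly spend per person and category
#'
#' The deterministic part of the expenditure model: for adults,
#' `participation * exp(log baseline + sum of attribute effects +
#' sdlog^2 / 2)` per category, times the regional price factor if the config
#' carries an RRCPL table; children spend zero.
#'
#' @param population Data frame with the microdata attribute columns and a
#'   `region` column.
#' @param config A `world_config`.
#' @return Persons x categories matrix of expected weekly pounds.
#' @export
latent_expenditure <- function(population, config) {
  cat_tab <- config$catalogue
  codes <- cat_tab$coicop
  n <- nrow(population)
  eta <- matrix(rep(log(cat_tab$baseline_gbp), each = n), n, length(codes),
                dimnames = list(NULL, codes))
  eff <- config$effects
  if (!is.null(eff) && nrow(eff)) {
    for (i in seq_len(nrow(eff))) {
      hit <- grepl(eff$label[i], population[[eff$variable[i]]])
      hit[is.na(hit)] <- FALSE
      j <- match(eff$coicop[i], codes)
      eta[hit, j] <- eta[hit, j] + eff$effect[i]
    }
  }
  lat <- exp(sweep(eta, 2, cat_tab$sdlog^2 / 2, `+`))
  lat <- sweep(lat, 2, cat_tab$participation, `*`)
  if (!is.null(config$rrcpl)) {
    pc <- price_category(codes)
    for (j in seq_along(codes)) {
      lat[, j] <- lat[, j] *
        rrcpl_index(config$rrcpl, population$region, pc[j]) / 100
    }
  }
  adult <- population$age_sex %in% .AGE_SEX_ADULT
  lat[!adult, ] <- 0
  lat
}

#' Draw the survey microdata and expenditure diary
#'
#' Samples `survey_size` individuals without replacement from the pooled
#' population (so the survey inherits the population mixture across zones),
#' assigns household.person ids, stamps a survey completion date in the
#' study year, and — crucially — drops the zone label, retaining only the
#' region: the survey is geocoded coarsely, exactly the situation
#' reweighting is for. Adults then record a weekly diary: for each category,
#' a purchase occurs with the category's participation probability and its
#' value is `exp(log baseline + attribute effects + Normal(0, sdlog) noise)`
#' (times the regional price factor); zero records are omitted.
#'
#' @param population From [generate_population()].
#' @param config The same `world_config`.
#' @return List with `microdata` (validated), `diary`, and
#'   `sampled_zone` (the true zone of each respondent, kept out of the
#'   microdata but returned for diagnostics).
#' @export
sample_survey <- function(population, config) {
  if (!nrow(population)) stop("population is empty")
  if (config$survey_size > nrow(population)) {
    stop("survey_size exceeds population size")
  }
  set.seed(config$seed + 1L)
  idx <- sample.int(nrow(population), config$survey_size)
  smp <- population[idx, , drop = FALSE]
  n <- nrow(smp)
  hh <- (seq_len(n) + 1L) %/% 2L
  per <- seq_len(n) - 2L * (hh - 1L)
  smp$id <- paste(hh, per, sep = ".")
  smp$survey_date <- as.Date(sprintf("%d-01-01", config$year)) +
    sample.int(365L, n, replace = TRUE) - 1L

  cat_tab <- config$catalogue
  codes <- cat_tab$coicop
  adult <- smp$age_sex %in% .AGE_SEX_ADULT
  eta <- .diary_eta(smp, config)          # log expected spend, no noise term

  recs <- vector("list", length(codes))
  for (j in seq_along(codes)) {
    buy <- adult & stats::runif(n) < cat_tab$participation[j]
    nb <- sum(buy)
    if (!nb) next
    val <- exp(eta[buy, j] + stats::rnorm(nb, 0, cat_tab$sdlog[j]))
    recs[[j]] <- data.frame(id = smp$id[buy], coicop = codes[j],
                            weekly_expenditure = round(val, 2),
                            stringsAsFactors = FALSE)
  }
  diary <- do.call(rbind, recs)
  if (is.null(diary)) {
    diary <- data.frame(id = character(0), coicop = character(0),
                        weekly_expenditure = numeric(0))
  }
  diary <- diary[order(diary$id, diary$coicop), , drop = FALSE]
  rownames(diary) <- NULL

  microdata <- smp[, c("id", "region", "age_sex", "ethnicity", "student",
                       "unemployed", "gross_weekly_wage", "employment_type",
                       "household_type", "survey_date")]
  rownames(microdata) <- NULL
  list(microdata = microdata, diary = diary,
       sampled_zone = stats::setNames(smp$zone_code, smp$id))
}

# log of the median spend (baseline + effects + regional price factor), i.e.
# the lognormal location parameter per sampled person and category
.diary_eta <- function(smp, config) {
  cat_tab <- config$catalogue
  codes <- cat_tab$coicop
  n <- nrow(smp)
  eta <- matrix(rep(log(cat_tab$baseline_gbp), each = n), n, length(codes),
                dimnames = list(NULL, codes))
  eff <- config$effects
  if (!is.null(eff) && nrow(eff)) {
    for (i in seq_len(nrow(eff))) {
      hit <- grepl(eff$label[i], smp[[eff$variable[i]]])
      hit[is.na(hit)] <- FALSE
      j <- match(eff$coicop[i], codes)
      eta[hit, j] <- eta[hit, j] + eff$effect[i]
    }
  }
  if (!is.null(config$rrcpl)) {
    pc <- price_category(codes)
    for (j in seq_along(codes)) {
      eta[, j] <- eta[, j] +
        log(rrcpl_index(config$rrcpl, smp$region, pc[j]) / 100)
    }
  }
  eta
}

#' Tabulate the exact constraint tables of a population
#'
#' Derives every constraint input from the simulated population by direct
#' counting, so the emitted marginals reproduce the truth exactly
#' (conservation): per-zone counts for adult age-sex, ethnicity, student,
#' unemployment and household type; the child age-sex table; and the income
#' inputs — per-zone P10...P80 employee-wage boundaries (type-7 linear
#' interpolation quantiles) plus employee / self-employed / other counts.
#'
#' @param population From [generate_population()] (or any data frame with the
#'   attribute columns plus `zone_code`).
#' @return List with `adult` (named list of raw `constraint_table`s),
#'   `income` (`boundaries` and `employment` data frames in the standard
#'   layout), `child` (age-sex `constraint_table`) and `baseline`
#'   (`adult`, `child` named totals).
#' @export
tabulate_constraints <- function(population) {
  adult <- population$age_sex %in% .AGE_SEX_ADULT
  ad <- population[adult, , drop = FALSE]
  ch <- population[!adult, , drop = FALSE]
  zones <- sort(unique(population$zone_code))

  count_tab <- function(df, col, levels, variable) {
    m <- table(factor(df$zone_code, levels = zones),
               factor(df[[col]], levels = levels))
    constraint_table(matrix(as.numeric(m), nrow = length(zones),
                            dimnames = list(zones, levels)), variable)
  }
  adult_tabs <- list(
    age_sex = count_tab(ad, "age_sex", .AGE_SEX_ADULT, "age_sex"),
    household_type = count_tab(ad, "household_type", .HOUSEHOLD_TYPE,
                               "household_type"),
    ethnicity = count_tab(ad, "ethnicity", .ETHNICITY, "ethnicity"),
    student = count_tab(ad, "student", .STUDENT, "student"),
    unemployment = count_tab(ad, "unemployed", .UNEMPLOYED, "unemployment")
  )

  probs <- seq(0.1, 0.8, 0.1)
  bnd <- t(vapply(zones, function(z) {
    w <- ad$gross_weekly_wage[ad$zone_code == z & ad$employment_type == "Employee"]
    if (length(w) < 2) rep(NA_real_, 8) else
      unname(stats::quantile(w, probs, type = 7))
  }, numeric(8)))
  colnames(bnd) <- paste0("p", seq(10, 80, 10))
  boundaries <- data.frame(zone_code = zones, bnd, row.names = NULL,
                           stringsAsFactors = FALSE)
  et <- table(factor(ad$zone_code, levels = zones),
              factor(ad$employment_type, levels = .EMPLOYMENT_TYPE))
  employment <- data.frame(zone_code = zones,
                           employees = as.numeric(et[, "Employee"]),
                           self_employed = as.numeric(et[, "Self-employed"]),
                           other = as.numeric(et[, "Other"]),
                           row.names = NULL, stringsAsFactors = FALSE)

  child_tab <- count_tab(ch, "age_sex", .AGE_SEX_CHILD, "age_sex")
  list(adult = adult_tabs,
       income = list(boundaries = boundaries, employment = employment),
       child = child_tab,
       baseline = list(adult = rowSums(adult_tabs$age_sex),
                       child = rowSums(child_tab)))
}

#' Regional survey means and standard errors from the diary
#'
#' The survey-averaging estimator used for external validation: for each
#' region and category, the mean weekly spend per adult respondent (zero
#' weeks included) with its sampling standard error.
#'
#' @param survey Result of [sample_survey()].
#' @param config The `world_config` (for the catalogue).
#' @return Data frame `region`, `coicop`, `mean`, `se`, `n`.
#' @export
survey_regional_stats <- function(survey, config) {
  md <- survey$microdata
  adult <- md$age_sex %in% .AGE_SEX_ADULT
  md <- md[adult, , drop = FALSE]
  codes <- config$catalogue$coicop
  out <- list()
  for (r in unique(md$region)) {
    ids <- md$id[md$region == r]
    n <- length(ids)
    d <- survey$diary[survey$diary$id %in% ids, , drop = FALSE]
    for (cc in codes) {
      x <- d$weekly_expenditure[d$coicop == cc]
      s1 <- sum(x); s2 <- sum(x^2)
      mu <- s1 / n
      va <- (s2 - n * mu^2) / (n - 1)
      out[[length(out) + 1L]] <- data.frame(
        region = r, coicop = cc, mean = mu, se = sqrt(va / n), n = n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
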