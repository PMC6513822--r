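# The synthetic world generator: determinism, distributional correctness and
# conservation between the population and its emitted constraint tables.

small_config <- function(...) {
  world_config(n_zones = 3, survey_size = 600,
               adult_populations = c(800, 1000, 1200), seed = 7, ...)
}

test_that("generation is bit-reproducible given the seed", {
  cfg <- small_config()
  w1 <- generate_population(cfg)
  w2 <- generate_population(cfg)
  expect_identical(w1, w2)
  s1 <- sample_survey(w1$population, cfg)
  s2 <- sample_survey(w2$population, cfg)
  expect_identical(s1, s2)
})

test_that("a degenerate categorical distribution yields identical records", {
  cfg <- world_config(n_zones = 1, survey_size = 600,
                      adult_populations = 100, child_populations = 0, seed = 3)
  cfg$attribute_distributions[[1]]$ethnicity <-
    c(white = 1, mixed = 0, black = 0, other = 0)
  pop <- generate_population(cfg)$population
  expect_equal(nrow(pop), 100)
  expect_true(all(pop$ethnicity == "white"))
})

test_that("zone category counts follow the configured probabilities", {
  cfg <- world_config(n_zones = 1, survey_size = 600,
                      adult_populations = 10000, child_populations = 0,
                      seed = 11)
  cfg$attribute_distributions[[1]]$student <-
    c(student = 0.3, `not-student` = 0.7)
  pop <- generate_population(cfg)$population
  n_student <- sum(pop$student == "student")
  sd3 <- 3 * sqrt(10000 * 0.3 * 0.7)
  expect_lt(abs(n_student - 3000), sd3)
})

test_that("an invalid distribution is rejected with the offending zone", {
  cfg <- small_config()
  cfg$attribute_distributions[[2]]$ethnicity <-
    c(white = 0.5, mixed = 0.4, black = 0.2, other = -0.1)
  expect_error(generate_population(cfg), "E06000002.*ethnicity")
})

test_that("emitted constraint marginals conserve the true population", {
  cfg <- small_config()
  world <- generate_population(cfg)
  pop <- world$population
  tabs <- world$ground_truth$true_population_tables
  adults <- pop[pop$age_sex %in% category_levels("age_sex"), ]
  # independent recount by nested loops
  for (v in c("age_sex", "ethnicity", "household_type")) {
    col <- if (v == "age_sex") "age_sex" else v
    tab <- tabs$adult[[v]]
    for (z in rownames(tab)) {
      for (k in colnames(tab)) {
        expect_equal(unname(tab[z, k]),
                     as.numeric(sum(adults$zone_code == z & adults[[col]] == k)))
      }
    }
  }
  # every table's per-zone total equals that zone's population
  for (v in names(tabs$adult)) {
    expect_equal(unname(rowSums(tabs$adult[[v]])),
                 unname(cfg$adult_populations), tolerance = 0)
  }
  emp <- tabs$income$employment
  expect_equal(emp$employees + emp$self_employed + emp$other,
               unname(cfg$adult_populations))
})

test_that("a single-person zone has exactly one nonzero unit cell per table", {
  cfg <- world_config(n_zones = 1, survey_size = 600, adult_populations = 1,
                      child_populations = 0, seed = 5)
  world <- generate_population(cfg)
  for (tab in world$ground_truth$true_population_tables$adult) {
    expect_equal(sum(tab != 0), 1)
    expect_equal(sum(tab), 1)
  }
})

test_that("zero noise and zero effects give zone-identical ground truth", {
  cat0 <- synthetic_catalogue()
  cat0$sdlog <- 0
  cat0$participation <- 1
  cfg <- world_config(n_zones = 4, survey_size = 600,
                      adult_populations = c(800, 1200, 1600, 2000),
                      child_populations = c(200, 300, 400, 500),
                      catalogue = cat0, effects = NULL, rrcpl = NULL, seed = 2)
  truth <- generate_population(cfg)$ground_truth$true_zone_expenditure
  for (j in seq_len(ncol(truth))) {
    expect_equal(max(truth[, j]) - min(truth[, j]), 0)
  }
  # and equal to baseline scaled by the adult share (children spend nothing)
  expect_equal(unname(truth[1, "1.1.1.1.1"]), 2.0 * 800 / 1000)
})

test_that("noise-free, effect-free diaries equal the category baselines", {
  cat0 <- synthetic_catalogue()
  cat0$sdlog <- 0
  cat0$participation <- 1
  cfg <- world_config(n_zones = 2, survey_size = 600,
                      adult_populations = c(700, 700),
                      child_populations = c(0, 0),
                      catalogue = cat0, effects = NULL, rrcpl = NULL, seed = 9)
  survey <- sample_survey(generate_population(cfg)$population, cfg)
  base <- setNames(cat0$baseline_gbp, cat0$coicop)
  expect_true(all(survey$diary$weekly_expenditure ==
                    base[survey$diary$coicop]))
})

test_that("diary means match the closed-form lognormal mean", {
  cfg <- world_config(n_zones = 1, survey_size = 12000,
                      adult_populations = 15000, child_populations = 0,
                      rrcpl = NULL, seed = 13)
  world <- generate_population(cfg)
  survey <- sample_survey(world$population, cfg)
  md <- survey$microdata
  # reference adults with no bread effects active: employed, not unemployed,
  # no dependent children
  ref <- md$id[md$unemployed == "not-unemployed" &
                 !grepl("dep_y", md$household_type)]
  d <- survey$diary[survey$diary$coicop == "1.1.1.1.1" &
                      survey$diary$id %in% ref, ]
  pred <- 2.0 * exp(0.45^2 / 2)
  se <- sd(d$weekly_expenditure) / sqrt(nrow(d))
  expect_gt(nrow(d), 5000)
  expect_lt(abs(mean(d$weekly_expenditure) - pred), 2 * se)
})

test_that("survey drops the zone label but keeps region; oversampling errors", {
  cfg <- small_config()
  world <- generate_population(cfg)
  survey <- sample_survey(world$population, cfg)
  expect_false("zone_code" %in% names(survey$microdata))
  expect_true(all(survey$microdata$region %in% category_levels("region")))
  expect_equal(nrow(survey$microdata), cfg$survey_size)
  big <- cfg
  big$survey_size <- nrow(world$population) + 1
  expect_error(sample_survey(world$population, big), "exceeds")
})

test_that("income boundaries equal sort-based type-7 quantiles", {
  cfg <- small_config()
  world <- generate_population(cfg)
  pop <- world$population
  bnd <- world$ground_truth$true_population_tables$income$boundaries
  z <- cfg$zones[2]
  w <- sort(pop$gross_weekly_wage[pop$zone_code == z &
                                    pop$employment_type == "Employee"])
  n <- length(w)
  for (i in 1:8) {
    p <- i / 10
    h <- (n - 1) * p + 1           # type-7 plotting position
    lo <- floor(h)
    q <- w[lo] + (h - lo) * (w[min(lo + 1, n)] - w[lo])
    expect_equal(bnd[bnd$zone_code == z, paste0("p", i * 10)], q,
                 tolerance = 1e-12)
  }
})

test_that("config invariants are enforced", {
  expect_error(world_config(n_zones = 2, survey_size = 100, seed = 1),
               "survey_size")
  cfg <- small_config()
  cfg$adult_populations[1] <- 0
  expect_error(validate_world_config(cfg), "positive")
})
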