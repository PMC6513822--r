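# Constraint construction: baseline subtraction, scaling, income brackets,
# and per-zone harmonisation of missing data.

mk_tab <- function(m, var = "age_sex") constraint_table(m, var)

test_that("baseline is midyear minus communal, cellwise", {
  my <- mk_tab(matrix(c(100, 50, 80, 70), 2, 2,
                      dimnames = list(c("Z1", "Z2"), c("F_25_34", "M_25_34"))))
  cm <- mk_tab(matrix(c(10, 0, 5, 70), 2, 2,
                      dimnames = list(c("Z1", "Z2"), c("F_25_34", "M_25_34"))))
  bl <- build_baseline(my, cm)
  expect_equal(unname(bl$constraint["Z1", ]), c(90, 75))
  expect_equal(unname(bl$constraint["Z2", "M_25_34"]), 0)  # boundary: all communal
  # summation oracle: totals equal explicit cell sums
  for (z in c("Z1", "Z2")) {
    expect_equal(unname(bl$baseline[z]), sum(bl$constraint[z, ]))
  }
  # identity when communal is zero
  expect_equal(unclass(build_baseline(my)$constraint), unclass(my))
  # clamping of inconsistent inputs
  cm2 <- cm; cm2["Z1", 1] <- 120
  expect_warning(bl2 <- build_baseline(my, cm2), "clamped")
  expect_equal(unname(bl2$constraint["Z1", 1]), 0)
})

test_that("scaling preserves proportions and hits the baseline exactly", {
  raw <- mk_tab(matrix(c(2, 30, 1, 50, 1, 20), 2, 3,
                       dimnames = list(c("Z1", "Z2"),
                                       c("white", "black", "other"))),
                "ethnicity")
  base <- c(Z1 = 400, Z2 = 1000)
  sc <- scale_constraint(raw, base)
  expect_equal(unname(rowSums(sc)), unname(base))
  expect_equal(unname(sc["Z1", ]) / sum(sc["Z1", ]),
               unname(raw["Z1", ]) / sum(raw["Z1", ]))
  # idempotence
  expect_equal(unclass(scale_constraint(sc, base)), unclass(sc))
  # invariance to positive rescaling of the raw input
  raw2 <- raw; raw2["Z2", ] <- raw["Z2", ] * 7
  expect_equal(unclass(scale_constraint(raw2, base)), unclass(sc))
  # zero rowsum marks the zone unavailable
  raw3 <- raw; raw3["Z1", ] <- 0
  sc3 <- scale_constraint(raw3, base)
  expect_true(all(is.na(sc3["Z1", ])))
  expect_equal(attr(sc3, "unavailable_zones"), "Z1")
})

test_that("income brackets: eight equal deciles plus one double top", {
  bnd <- data.frame(zone_code = "Z1", p10 = 100, p20 = 150, p30 = 200,
                    p40 = 250, p50 = 300, p60 = 350, p70 = 400, p80 = 450)
  emp <- data.frame(zone_code = "Z1", employees = 900, self_employed = 50,
                    other = 50)
  inc <- build_income_constraint(bnd, emp, c(Z1 = 1000))
  pre <- inc$prescale$Z1
  dec <- pre[paste0("P", seq(0, 70, 10), "_P", seq(10, 80, 10))]
  expect_equal(unname(dec), rep(90, 8))
  expect_equal(unname(pre["P80_P100"]), 180)    # exactly double a decile
  expect_equal(unname(pre[c("self_employed", "other")]), c(50, 50))
  expect_equal(sum(inc$zone_targets$Z1), 1000)
})

test_that("zero employees push all mass to self-employed and other", {
  bnd <- data.frame(zone_code = "Z1", p10 = NA, p20 = NA, p30 = NA, p40 = NA,
                    p50 = NA, p60 = NA, p70 = NA, p80 = NA)
  emp <- data.frame(zone_code = "Z1", employees = 0, self_employed = 30,
                    other = 70)
  inc <- build_income_constraint(bnd, emp, c(Z1 = 500))
  tz <- inc$zone_targets$Z1
  expect_equal(unname(tz["P0_P100"]), 0)
  expect_equal(unname(tz["self_employed"]), 150)
  expect_equal(unname(tz["other"]), 350)
})

test_that("missing boundaries merge adjacent brackets", {
  bnd <- data.frame(zone_code = "Z1", p10 = 100, p20 = 150, p30 = NA,
                    p40 = 250, p50 = 300, p60 = 350, p70 = 400, p80 = 450)
  emp <- data.frame(zone_code = "Z1", employees = 1000, self_employed = 0,
                    other = 0)
  expect_message(inc <- build_income_constraint(bnd, emp, c(Z1 = 1000)),
                 "merged")
  pre <- inc$prescale$Z1
  expect_true("P20_P40" %in% names(pre))
  expect_equal(unname(pre["P20_P40"]), 200)       # two deciles pooled
  expect_equal(sum(pre), 1000)
  # non-monotone boundaries mark the zone unavailable
  bad <- bnd; bad$p30 <- 90
  expect_warning(inc2 <- build_income_constraint(bad, emp, c(Z1 = 1000)),
                 "non-monotone")
  expect_null(inc2$zone_targets$Z1)
})

test_that("wages classify into zone brackets with left-closed boundaries", {
  b <- c(100, 150, 200, 250, 300, 350, 400, 450)
  expect_equal(income_category(c(50, 100, 449, 450, 9999),
                               rep("Employee", 5), b),
               c("P0_P10", "P10_P20", "P70_P80", "P80_P100", "P80_P100"))
  expect_equal(income_category(c(0, 700), c("Self-employed", "Other"), b),
               c("self_employed", "other"))
})

test_that("harmonisation drops binaries and merges partial ethnicity", {
  md <- data.frame(
    id = as.character(1:8), region = "Wales",
    age_sex = rep(c("F_25_34", "M_25_34"), 4),
    ethnicity = c("white", "white", "mixed", "other",
                  "black", "white", "mixed", "white"),
    student = rep(c("student", "not-student"), 4),
    unemployed = "not-unemployed", gross_weekly_wage = 300,
    employment_type = "Employee",
    household_type = rep(c("25_34_dep_n", "55_64_sph"), 4),
    stringsAsFactors = FALSE)
  zones <- c("Z1", "Z2")
  base <- c(Z1 = 100, Z2 = 200)
  cons <- list(
    age_sex = mk_tab(matrix(c(50, 100, 50, 100), 2, 2,
                            dimnames = list(zones, c("F_25_34", "M_25_34")))),
    household_type = mk_tab(matrix(c(60, 120, 40, 80), 2, 2,
                                   dimnames = list(zones, c("25_34_dep_n",
                                                            "55_64_sph"))),
                            "household_type"),
    ethnicity = mk_tab(matrix(c(70, 150, NA, 20, 10, 10, 20, 20), 2, 4,
                              dimnames = list(zones, c("white", "mixed",
                                                       "black", "other"))),
                       "ethnicity"),
    student = mk_tab(matrix(c(30, NA, 70, NA), 2, 2,
                            dimnames = list(zones,
                                            c("student", "not-student"))),
                     "student"))
  plan <- harmonise_missing(md, cons, base)
  v1 <- vapply(plan$zone$Z1, `[[`, "", "variable")
  v2 <- vapply(plan$zone$Z2, `[[`, "", "variable")
  expect_true("student" %in% v1)
  expect_false("student" %in% v2)          # all-NA row dropped for Z2
  e1 <- plan$zone$Z1[[which(v1 == "ethnicity")]]
  expect_equal(names(e1$targets), c("white", "black", "other"))
  expect_equal(sum(e1$targets), 100)       # rescaled to baseline
  # the zone's mixed individuals are counted under the catch-all
  mixed_idx <- which(md$ethnicity == "mixed")
  expect_equal(unique(names(e1$targets)[e1$cats[mixed_idx]]), "other")
  # Z2 keeps all four categories
  e2 <- plan$zone$Z2[[which(v2 == "ethnicity")]]
  expect_equal(length(e2$targets), 4)
  expect_true(any(grepl("merged", plan$notes$action)))
})

test_that("model runs on age-sex and household type as a minimum", {
  toy <- toy_2x2()
  fit <- ipf_fit(toy$md, toy$cons, toy$baseline)
  expect_true(fit$diagnostics$converged)
  # but age_sex itself is indispensable
  expect_error(harmonise_missing(toy$md, toy$cons["household_type"],
                                 toy$baseline),
               "age_sex")
})

test_that("constraint availability audit counts zones per variable", {
  manifest <- data.frame(zone_code = c("A", "B", "C", "A", "B", "C"),
                         year = rep(c(2008, 2009), each = 3),
                         age_sex = TRUE, household_type = TRUE,
                         student = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
                         income = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  aud <- audit_constraints(manifest)
  expect_equal(aud$age_sex, c(3L, 3L))
  expect_equal(aud$student, c(2L, 3L))
  expect_equal(aud$income, c(2L, 2L))
})
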