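# The IPF core: exactness, convergence, closed forms and oracles.

test_that("matching microdata proportions give uniform weights in one sweep", {
  toy <- toy_2x2(age_targets = c(F_25_34 = 50, M_25_34 = 50),
                 hh_targets = c(`25_34_dep_n` = 50, `55_64_sph` = 50))
  fit <- ipf_fit(toy$md, toy$cons, toy$baseline, max_iter = 1)
  expect_equal(unname(fit$weights[, 1]), rep(25, 4))
})

test_that("the 2x2 fit equals brute-force matrix scaling", {
  toy <- toy_2x2(age_targets = c(F_25_34 = 60, M_25_34 = 40),
                 hh_targets = c(`25_34_dep_n` = 70, `55_64_sph` = 30))
  fit <- ipf_fit(toy$md, toy$cons, toy$baseline, tol = 1e-12, max_iter = 500)
  # independent oracle: scale a 2x2 seed array of ones to the margins
  oracle <- scale_2x2(matrix(1, 2, 2), c(60, 40), c(70, 30))
  # rows: F/M; cols: dep_n/sph. individuals 1.1=(F,dep_n), 1.2=(F,sph), ...
  expect_equal(unname(fit$weights[c("1.1", "1.2", "2.1", "2.2"), 1]),
               c(oracle[1, 1], oracle[1, 2], oracle[2, 1], oracle[2, 2]),
               tolerance = 1e-9)
})

test_that("the marginal updated last matches its target to machine precision", {
  # an unbalanced cell (two individuals in F/dep_n) so the unit-weight seed
  # is not already product-form and one sweep cannot satisfy both margins
  toy <- toy_2x2()
  md5 <- rbind(toy$md,
               data.frame(id = "3.1", region = "Wales", age_sex = "F_25_34",
                          ethnicity = "white", student = "not-student",
                          unemployed = "not-unemployed",
                          gross_weekly_wage = 400,
                          employment_type = "Employee",
                          household_type = "25_34_dep_n"))
  fit <- ipf_fit(md5, toy$cons, toy$baseline, max_iter = 1)
  res_hh <- residuals(fit, "household_type")
  expect_lt(max(abs(res_hh)), 1e-10)
  # while the earlier constraint has been perturbed away from its target
  expect_gt(max(abs(residuals(fit, "age_sex"))), 1e-3)
})

test_that("TAE is nonincreasing across sweeps and convergence is reached", {
  fw <- full_world()
  tae <- rowSums(fw$fit$diagnostics$tae)
  expect_true(all(diff(tae) <= tae[-length(tae)] * 1e-12 + 1e-8))
  expect_true(fw$fit$diagnostics$converged)
  expect_lte(fw$fit$diagnostics$iterations, 50)
  # converged marginals match every constraint within tolerance
  for (v in c("age_sex", "household_type", "ethnicity", "student",
              "unemployment", "income")) {
    r <- residuals(fw$fit, v)
    rel <- rowSums(abs(r), na.rm = TRUE) / fw$bl$baseline[rownames(r)]
    expect_lt(max(rel), 1e-4)
  }
})

test_that("per-zone weight sums equal the baseline after convergence", {
  fw <- full_world()
  sums <- colSums(fw$fit$weights)
  expect_equal(unname(sums), unname(fw$bl$baseline[names(sums)]),
               tolerance = 1e-4)
  expect_true(all(fw$fit$weights >= 0))
})

test_that("weights are invariant to microdata row permutation", {
  toy <- toy_2x2()
  md8 <- rbind(toy$md, transform(toy$md, id = paste0(id, "b")))
  fit1 <- ipf_fit(md8, toy$cons, toy$baseline, tol = 1e-10)
  perm <- c(5, 2, 7, 4, 1, 6, 3, 8)
  fit2 <- ipf_fit(md8[perm, ], toy$cons, toy$baseline, tol = 1e-10)
  expect_equal(fit2$weights[rownames(fit1$weights), , drop = FALSE],
               fit1$weights)
})

test_that("simulated marginals equal a naive double-loop summation", {
  set.seed(4)
  W <- matrix(runif(60), 12, 5,
              dimnames = list(paste0("i", 1:12), paste0("z", 1:5)))
  cats <- sample(c("a", "b", "c"), 12, TRUE)
  m <- simulated_marginals(W, cats)
  for (z in colnames(W)) {
    for (k in c("a", "b", "c")) {
      acc <- 0
      for (i in rownames(W)) if (cats[match(i, rownames(W))] == k) {
        acc <- acc + W[i, z]
      }
      expect_equal(unname(m[z, k]), acc)
    }
  }
  # unit weights with singleton categories count each individual once
  W1 <- matrix(1, 3, 2, dimnames = list(letters[1:3], c("z1", "z2")))
  m1 <- simulated_marginals(W1, c("u", "v", "w"))
  expect_true(all(m1 == 1))
})

test_that("the child model matches its closed form and the generic fitter", {
  con <- constraint_table(
    matrix(c(40, 80, 30, 60, 50, 100, 20, 40), 2, 4,
           dimnames = list(c("Z1", "Z2"), category_levels("age_sex_child"))),
    "age_sex")
  kids <- data.frame(
    id = as.character(1:8),
    age_sex = rep(category_levels("age_sex_child"), each = 2),
    stringsAsFactors = FALSE)
  fit <- fit_child_model(kids, con)
  # closed form: target / microdata count per category
  for (z in c("Z1", "Z2")) {
    for (i in seq_len(8)) {
      k <- kids$age_sex[i]
      expect_equal(unname(fit$weights[as.character(i), z]),
                   unname(con[z, k]) / 2)
    }
  }
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$diagnostics$iterations, 1L)
  # single child per category carries the whole target
  kids1 <- kids[c(1, 3, 5, 7), ]
  fit1 <- fit_child_model(kids1, con)
  expect_equal(unname(fit1$weights[, "Z1"]),
               unname(con["Z1", kids1$age_sex]))
  # and a one-sweep single-constraint generic IPF agrees exactly
  kids_md <- data.frame(id = kids$id, region = "Wales",
                        age_sex = kids$age_sex, ethnicity = "white",
                        student = "not-student",
                        unemployed = "not-unemployed",
                        gross_weekly_wage = 0, employment_type = "Other",
                        household_type = "25_34_dep_n",
                        stringsAsFactors = FALSE)
  g <- ipf_fit(kids_md, list(age_sex = con, household_type = constraint_table(
    matrix(rowSums(con), 2, 1,
           dimnames = list(c("Z1", "Z2"), "25_34_dep_n")), "household_type")),
    rowSums(con), order = c("household_type", "age_sex"), max_iter = 1)
  expect_equal(g$weights, fit$weights)
})

test_that("a positive-target category with no children is an error", {
  con <- constraint_table(
    matrix(1:8, 2, 4, dimnames = list(c("Z1", "Z2"),
                                      category_levels("age_sex_child"))),
    "age_sex")
  kids <- data.frame(id = "1", age_sex = "F_0_9", stringsAsFactors = FALSE)
  expect_error(fit_child_model(kids, con), "no sampled children")
})

test_that("empty cells are dropped with rescaling, or error in strict mode", {
  toy <- toy_2x2()
  cons <- toy$cons
  # add an ethnicity constraint with a category no individual holds
  cons$ethnicity <- constraint_table(
    matrix(c(80, 20), 1, 2, dimnames = list("Z1", c("white", "black"))),
    "ethnicity")
  expect_warning(fit <- ipf_fit(toy$md, cons, toy$baseline), "empty")
  e <- fit$plan$zone$Z1
  eth <- e[[which(vapply(e, `[[`, "", "variable") == "ethnicity")]]
  expect_equal(names(eth$targets), "white")
  expect_equal(unname(eth$targets), 100)   # rescaled to baseline
  expect_error(
    suppressWarnings(ipf_fit(toy$md, cons, toy$baseline,
                             empty_cells = "error")),
    "empty cell")
})

test_that("non-convergence is reported honestly", {
  toy <- toy_2x2()
  fit <- ipf_fit(toy$md, toy$cons, toy$baseline, max_iter = 1, tol = 1e-12)
  expect_false(fit$diagnostics$converged)
})

test_that("fit methods expose weights, marginals and diagnostics", {
  toy <- toy_2x2()
  fit <- ipf_fit(toy$md, toy$cons, toy$baseline, tol = 1e-10)
  expect_identical(coef(fit), fit$weights)
  expect_equal(unname(predict(fit, "age_sex")["Z1", ]),
               unname(toy$cons$age_sex["Z1", ]), tolerance = 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.msim_fit")
  expect_output(print(s), "converged")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
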