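# Iterative proportional fitting of individual weights to zone constraints.

#' Fit individual-to-zone weights by iterative proportional fitting
#'
#' The workhorse of the package. Starting from unit weights for every
#' (individual, zone) pair — no initial geographical restriction, so any
#' individual may serve any zone — IPF cycles through the constraint
#' variables in a declared order and, for each zone and constraint,
#' multiplies the weights of each category's individuals by
#' `target / simulated` so that the simulated marginal for that constraint
#' matches its target exactly. Repeated sweeps converge towards weights
#' consistent with all constraints simultaneously. Weights stay fractional
#' throughout: the targets are real-valued scaled counts and the outputs are
#' expenditure means, so no integerisation is applied.
#'
#' Income is a zone-specific classification: each zone has its own wage
#' bracket boundaries, so an individual's income category is recomputed per
#' zone (handled by the plan; see [harmonise_missing()]).
#'
#' Convergence is declared when, at the start of a sweep, the maximum over
#' constraints and zones of total absolute error (TAE) relative to the zone
#' baseline falls below `tol`.
#'
#' @param microdata Validated adult microdata, or a prebuilt `msim_plan` (in
#'   which case `constraints`, `income` and `manifest` are ignored).
#' @param constraints Named list of scaled `constraint_table`s.
#' @param baseline Named per-zone baseline totals.
#' @param income Optional [build_income_constraint()] result.
#' @param manifest Optional availability manifest (see [harmonise_missing()]).
#' @param order Constraint update order. The fixed point of IPF does not
#'   depend on the order, but the iterate path does, so a declared order
#'   keeps runs deterministic.
#' @param max_iter Maximum number of full constraint sweeps.
#' @param tol Convergence tolerance on max per-zone TAE / baseline.
#' @param empty_cells Empty-cell strategy, `"drop"` or `"error"`.
#' @return An object of class `msim_fit` with components `weights`
#'   (individuals x zones matrix), `plan`, `baseline` and `diagnostics`
#'   (iterations, convergence flag, per-sweep TAE per constraint, per-zone
#'   relative TAE). Methods: [print.msim_fit()], [summary.msim_fit()],
#'   [coef.msim_fit()], [predict.msim_fit()], [residuals.msim_fit()],
#'   [plot.msim_fit()].
#' @seealso [fit_child_model()] for the single-constraint child model,
#'   [internal_validation()] for per-zone fit correlations.
#' @examples
#' md <- data.frame(
#'   id = c("1.1", "1.2", "2.1", "2.2"), region = "Wales",
#'   age_sex = c("F_25_34", "F_50_64", "M_25_34", "M_50_64"),
#'   ethnicity = "white", student = "not-student",
#'   unemployed = "not-unemployed", gross_weekly_wage = 400,
#'   employment_type = "Employee",
#'   household_type = c("25_34_dep_n", "55_64_sph", "25_34_dep_n", "55_64_sph")
#' )
#' con <- constraint_table(
#'   matrix(c(30, 20, 25, 25), 1, 4,
#'          dimnames = list("Z1", c("F_25_34", "F_50_64", "M_25_34", "M_50_64"))),
#'   "age_sex")
#' hh <- constraint_table(
#'   matrix(c(55, 45), 1, 2, dimnames = list("Z1", c("25_34_dep_n", "55_64_sph"))),
#'   "household_type")
#' fit <- ipf_fit(md, list(age_sex = con, household_type = hh),
#'                baseline = c(Z1 = 100))
#' coef(fit)
#' @export
ipf_fit <- function(microdata, constraints = NULL, baseline = NULL,
                    income = NULL, manifest = NULL,
                    order = .CONSTRAINT_VARS,
                    max_iter = 50L, tol = 1e-4,
                    empty_cells = c("drop", "error")) {
  cl <- match.call()
  if (inherits(microdata, "msim_plan")) {
    plan <- microdata
    if (is.null(baseline)) stop("baseline is required")
  } else {
    plan <- harmonise_missing(microdata, constraints, baseline, income,
                              manifest, order, match.arg(empty_cells))
  }
  zones <- plan$zones
  n <- length(plan$ids)
  W <- matrix(1, n, length(zones), dimnames = list(plan$ids, zones))

  vars <- intersect(plan$order, unique(unlist(lapply(plan$zone, function(es)
    vapply(es, `[[`, "", "variable")))))
  tae_hist <- NULL
  converged <- FALSE
  iter <- 0L
  zone_rel_tae <- stats::setNames(numeric(length(zones)), zones)

  for (sweep in seq_len(max_iter)) {
    iter <- sweep
    sweep_tae <- stats::setNames(rep(0, length(vars)), vars)
    worst_rel <- 0
    for (zi in seq_along(zones)) {
      z <- zones[zi]
      w <- W[, zi]
      entries <- plan$zone[[zi]]
      rel_z <- 0
      for (e in entries) {
        k <- length(e$targets)
        ok <- !is.na(e$cats)
        sim <- .wtab(w[ok], e$cats[ok], k)
        err <- sum(abs(sim - e$targets))
        sweep_tae[e$variable] <- sweep_tae[e$variable] + err
        rel_z <- max(rel_z, err / baseline[z])
        fac <- e$targets / sim
        fac[!is.finite(fac)] <- 1   # simulated mass vanished; leave untouched
        w[ok] <- w[ok] * fac[e$cats[ok]]
      }
      zone_rel_tae[zi] <- rel_z
      W[, zi] <- w
      worst_rel <- max(worst_rel, rel_z)
    }
    tae_hist <- rbind(tae_hist, sweep_tae)
    if (worst_rel < tol) {
      converged <- TRUE
      break
    }
  }
  rownames(tae_hist) <- seq_len(nrow(tae_hist))

  structure(list(weights = W, plan = plan, baseline = baseline,
                 diagnostics = list(iterations = iter, converged = converged,
                                    tol = tol, tae = tae_hist,
                                    zone_rel_tae = zone_rel_tae),
                 call = cl),
            class = "msim_fit")
}

# weighted tabulation: sum of w by integer category 1..k
.wtab <- function(w, cats, k) {
  out <- numeric(k)
  s <- rowsum(w, cats, reorder = FALSE)
  out[as.integer(rownames(s))] <- s
  out
}

#' Simulated marginal counts from a weight matrix
#'
#' Aggregates weights into zone x category counts for one classification:
#' `counts[z, k]` is the sum of weights over individuals in category `k` for
#' zone `z`. This is the "simulated" side of internal validation.
#'
#' @param weights Individuals x zones weight matrix.
#' @param categories Character or factor vector of category labels, one per
#'   individual (row of `weights`).
#' @return Zones x categories matrix of weighted counts.
#' @export
simulated_marginals <- function(weights, categories) {
  if (length(categories) != nrow(weights)) {
    stop("categories must have one entry per weight-matrix row")
  }
  f <- factor(categories)
  t(rowsum(weights, f, reorder = TRUE))
}

#' Fit the child model
#'
#' Children (15 and under) are constrained by a single age-sex variable with
#' four categories, so IPF converges in one sweep and admits a closed form:
#' every child in category `k` gets weight `target[z, k] / n_k`, where `n_k`
#' is the number of sampled children in that category.
#'
#' @param microdata Child microdata (rows with child `age_sex` labels).
#' @param constraint Scaled child age-sex `constraint_table` (four columns).
#' @return An `msim_fit` (converged, one iteration).
#' @export
fit_child_model <- function(microdata, constraint) {
  constraint <- as_constraint(constraint, "age_sex")
  labels <- colnames(constraint)
  cats <- match(microdata$age_sex, labels)
  if (anyNA(cats)) stop("child microdata has labels outside the constraint")
  nk <- tabulate(cats, nbins = length(labels))
  empty <- nk == 0 & colSums(constraint) > 0
  if (any(empty)) {
    stop("child categories with positive target but no sampled children: ",
         paste(labels[empty], collapse = ", "))
  }
  W <- t(unclass(constraint)[, cats, drop = FALSE]) / nk[cats]
  dimnames(W) <- list(as.character(microdata$id), rownames(constraint))
  baseline <- rowSums(constraint)
  plan <- structure(list(zones = rownames(constraint),
                         ids = as.character(microdata$id),
                         zone = stats::setNames(lapply(rownames(constraint), function(z)
                           list(list(variable = "age_sex",
                                     targets = constraint[z, ], cats = cats))),
                           rownames(constraint)),
                         order = "age_sex",
                         notes = data.frame(zone_code = character(0),
                                            variable = character(0),
                                            action = character(0))),
                    class = "msim_plan")
  structure(list(weights = W, plan = plan, baseline = baseline,
                 diagnostics = list(iterations = 1L, converged = TRUE,
                                    tol = 0,
                                    tae = matrix(0, 1, 1,
                                                 dimnames = list("1", "age_sex")),
                                    zone_rel_tae = stats::setNames(
                                      rep(0, nrow(constraint)),
                                      rownames(constraint))),
                 call = match.call()),
            class = "msim_fit")
}
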