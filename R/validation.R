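# Internal and external validation of a microsimulation run.

#' Internal validation: per-zone target vs simulated correlation
#'
#' For each zone, concatenates the target counts of every effective
#' constraint (in the declared fitting order) and the corresponding simulated
#' marginal counts from the fitted weights, and reports their Pearson
#' correlation. A well-posed converged fit gives correlations of 1 to several
#' decimals; departures flag empty cells or inconsistent constraints.
#' Per-constraint correlations are attached for debugging.
#'
#' @param fit An `msim_fit`.
#' @return Data frame `zone_code`, `r` (`NA` where a zone's target vector has
#'   zero variance, reported as undefined rather than 1), with a
#'   `per_constraint` attribute (zones x variables matrix of correlations).
#' @export
internal_validation <- function(fit) {
  zones <- fit$plan$zones
  vars <- .fit_variables(fit)
  per_con <- matrix(NA_real_, length(zones), length(vars),
                    dimnames = list(zones, vars))
  r <- stats::setNames(rep(NA_real_, length(zones)), zones)
  for (zi in seq_along(zones)) {
    tgt_all <- sim_all <- numeric(0)
    for (e in fit$plan$zone[[zi]]) {
      ok <- !is.na(e$cats)
      sim <- .wtab(fit$weights[ok, zi], e$cats[ok], length(e$targets))
      tgt_all <- c(tgt_all, e$targets)
      sim_all <- c(sim_all, sim)
      if (stats::sd(e$targets) > 0 && stats::sd(sim) > 0) {
        per_con[zi, e$variable] <- stats::cor(e$targets, sim)
      }
    }
    if (stats::sd(tgt_all) > 0 && stats::sd(sim_all) > 0) {
      r[zi] <- stats::cor(tgt_all, sim_all)
    }
  }
  out <- data.frame(zone_code = zones, r = unname(r), stringsAsFactors = FALSE)
  attr(out, "per_constraint") <- per_con
  out
}

#' External validation against regional survey means
#'
#' Aggregates the zone-level estimates to regions (population-weighted mean
#' over the zones of each region) and compares them with independently
#' computed survey means, flagging whether each simulated mean falls inside
#' the survey mean plus/minus 1.96 standard errors.
#'
#' @param estimates An `expenditure_estimate` (long form).
#' @param zone_populations Named per-zone total populations (the per-capita
#'   denominators).
#' @param region_of_zone Named zone -> region mapping.
#' @param survey Data frame `region`, `coicop`, `mean`, `se` (optionally
#'   `year`).
#' @return Data frame `region`, `coicop`, `simulated_mean`, `survey_mean`,
#'   `survey_se`, `within_95ci`.
#' @export
regional_comparison <- function(estimates, zone_populations, region_of_zone,
                                survey) {
  est <- estimates
  est$region <- region_of_zone[est$zone_code]
  if (anyNA(est$region)) stop("estimate zones missing from region_of_zone")
  est$pop <- zone_populations[est$zone_code]
  key <- paste(est$region, est$coicop, sep = "\r")
  num <- rowsum(est$pop * est$mean_weekly_expenditure_gbp, key, reorder = TRUE)
  den <- rowsum(est$pop, key, reorder = TRUE)
  sim <- data.frame(key = rownames(num), simulated_mean = num[, 1] / den[, 1],
                    stringsAsFactors = FALSE, row.names = NULL)
  skey <- paste(survey$region, survey$coicop, sep = "\r")
  m <- match(skey, sim$key)
  if (anyNA(m)) {
    bad <- unique(survey$region[is.na(m)])
    stop("region(s)/categorie(s) absent from estimates: ",
         paste(bad, collapse = ", "))
  }
  out <- data.frame(region = survey$region, coicop = survey$coicop,
                    simulated_mean = sim$simulated_mean[m],
                    survey_mean = survey$mean, survey_se = survey$se,
                    stringsAsFactors = FALSE)
  out$within_95ci <- abs(out$simulated_mean - out$survey_mean) <=
    1.96 * out$survey_se
  out
}

#' Spearman rank correlation against an external ranking
#'
#' Rank-correlates a set of zone estimates with an external zone ranking
#' (e.g. a deprivation index). Ties take average ranks; the two-sided p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors over the same zones (named vectors are aligned
#'   by name; at least 3 complete pairs required).
#' @return List with `rho`, `p_value`, `n`. `rho` is `NA` when either input
#'   is entirely tied (undefined).
#' @export
rank_correlation <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 zones with both values")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
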