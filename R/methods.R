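# S3 methods for the fitted reweighting model.

#' @export
print.msim_fit <- function(x, ...) {
  d <- x$diagnostics
  cat("Spatial microsimulation fit (IPF)\n")
  cat(sprintf("  %d individuals x %d zones\n", nrow(x$weights), ncol(x$weights)))
  cat(sprintf("  %d sweep(s); %s (tol %g, max rel. TAE %.3g)\n",
              d$iterations,
              if (d$converged) "converged" else "NOT converged",
              d$tol, max(d$zone_rel_tae)))
  invisible(x)
}

#' Summarise a microsimulation fit
#'
#' Reports convergence, final total absolute error per constraint, and the
#' distribution over zones of the internal-validation correlation between
#' constraint targets and simulated marginals.
#'
#' @param object An `msim_fit`.
#' @param ... Unused.
#' @export
summary.msim_fit <- function(object, ...) {
  d <- object$diagnostics
  iv <- internal_validation(object)
  structure(list(n_individuals = nrow(object$weights),
                 n_zones = ncol(object$weights),
                 iterations = d$iterations, converged = d$converged,
                 tol = d$tol,
                 final_tae = d$tae[nrow(d$tae), ],
                 zone_correlation = stats::setNames(iv$r, iv$zone_code)),
            class = "summary.msim_fit")
}

#' @export
print.summary.msim_fit <- function(x, ...) {
  cat("Spatial microsimulation fit (IPF)\n")
  cat(sprintf("  %d individuals x %d zones; %d sweep(s); %s\n",
              x$n_individuals, x$n_zones, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat("  Final TAE by constraint:\n")
  print(round(x$final_tae, 4))
  cat("  Per-zone internal-validation correlation:\n")
  print(summary(x$zone_correlation))
  invisible(x)
}

#' Extract fitted weights
#'
#' The estimated quantities of the model are the nonnegative fractional
#' weights linking each survey individual to each zone.
#'
#' @param object An `msim_fit`.
#' @param ... Unused.
#' @return Individuals x zones numeric matrix.
#' @export
coef.msim_fit <- function(object, ...) object$weights

#' Simulated marginals for a fitted model
#'
#' Returns the weighted category counts per zone for one constraint
#' variable, honouring zone-specific categorisations (income brackets,
#' merged categories).
#'
#' @param object An `msim_fit`.
#' @param variable Constraint variable name; defaults to the first fitted.
#' @param ... Unused.
#' @return Zones x categories matrix (categories are the union over zones;
#'   cells a zone does not use are `NA`).
#' @export
predict.msim_fit <- function(object, variable = NULL, ...) {
  .marginal_vs_target(object, variable)$simulated
}

#' Constraint residuals for a fitted model
#'
#' Target minus simulated marginal counts per zone and category for one
#' constraint variable. Near-zero residuals on every constraint indicate a
#' converged, well-posed fit.
#'
#' @param object An `msim_fit`.
#' @param variable Constraint variable name; defaults to the first fitted.
#' @param ... Unused.
#' @return Zones x categories matrix of `target - simulated`.
#' @export
residuals.msim_fit <- function(object, variable = NULL, ...) {
  m <- .marginal_vs_target(object, variable)
  m$target - m$simulated
}

.fit_variables <- function(object) {
  unique(unlist(lapply(object$plan$zone, function(es)
    vapply(es, `[[`, "", "variable"))))
}

.marginal_vs_target <- function(object, variable = NULL) {
  vars <- .fit_variables(object)
  if (is.null(variable)) variable <- vars[1L]
  if (!variable %in% vars) stop("variable not in fit: ", variable)
  zones <- object$plan$zones
  cats <- unique(unlist(lapply(zones, function(z) {
    for (e in object$plan$zone[[z]]) if (e$variable == variable) return(names(e$targets))
    NULL
  })))
  sim <- tgt <- matrix(NA_real_, length(zones), length(cats),
                       dimnames = list(zones, cats))
  for (zi in seq_along(zones)) {
    for (e in object$plan$zone[[zi]]) {
      if (e$variable != variable) next
      ok <- !is.na(e$cats)
      s <- .wtab(object$weights[ok, zi], e$cats[ok], length(e$targets))
      sim[zi, names(e$targets)] <- s
      tgt[zi, names(e$targets)] <- e$targets
    }
  }
  list(simulated = sim, target = tgt)
}

#' Plot IPF convergence
#'
#' Total absolute error per constraint against sweep number, on a log scale.
#'
#' @param x An `msim_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.msim_fit <- function(x, ...) {
  tae <- x$diagnostics$tae
  tae_plot <- pmax(tae, .Machine$double.xmin)
  graphics::matplot(seq_len(nrow(tae)), tae_plot, type = "b", log = "y",
                    pch = seq_len(ncol(tae)), lty = 1,
                    xlab = "sweep", ylab = "total absolute error",
                    main = "IPF convergence", ...)
  graphics::legend("topright", colnames(tae), pch = seq_len(ncol(tae)),
                   col = seq_len(ncol(tae)), lty = 1, bty = "n")
  invisible(x)
}
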