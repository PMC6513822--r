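# Per-zone harmonisation of constraints and microdata ahead of IPF.
#
# Not every zone has every constraint: binary variables (student,
# unemployment) are available or not, while ethnicity and income can be
# partially complete. The plan built here resolves, for every zone, the
# effective constraint list, the target vector for each constraint, and each
# microdata individual's category index under that constraint — merging
# missing categories into a catch-all and dropping empty cells as needed.

.MICRO_COL <- c(age_sex = "age_sex", household_type = "household_type",
                ethnicity = "ethnicity", student = "student",
                unemployment = "unemployed")

#' Harmonise constraints and microdata into a per-zone fitting plan
#'
#' Resolves constraint availability zone by zone and aligns the microdata
#' categories with each zone's effective targets. Age-sex and household type
#' must be available everywhere (the model runs on these as a minimum);
#' binary variables are dropped for zones lacking them; partially complete
#' ethnicity is re-categorised by merging each missing category into a
#' present catch-all (`"other"`, falling back to `"white"`), with the zone's
#' microdata re-labelled identically; income brackets may be merged at
#' missing boundaries (see [build_income_constraint()]). Constraint
#' categories with a positive target but no microdata individuals ("empty
#' cells") are dropped with the remaining targets rescaled to the baseline,
#' or raise an error in strict mode.
#'
#' @param microdata Validated adult microdata (see [validate_microdata()]).
#' @param constraints Named list of scaled `constraint_table`s (any of
#'   `age_sex`, `household_type`, `ethnicity`, `student`, `unemployment`).
#' @param baseline Named per-zone baseline totals.
#' @param income Optional result of [build_income_constraint()].
#' @param manifest Optional availability manifest: data frame with
#'   `zone_code` and one logical column per variable. Defaults to everything
#'   available; rows of all-`NA` targets are treated as unavailable
#'   regardless.
#' @param order Constraint update order (also the concatenation order used in
#'   internal validation).
#' @param empty_cells `"drop"` (default) or `"error"`.
#' @return An `msim_plan`: list with `zones`, `ids`, per-zone constraint
#'   entries (`zone[[z]]` is a list of `list(variable, targets, cats)`), and
#'   a `notes` data frame recording every per-zone adjustment.
#' @export
harmonise_missing <- function(microdata, constraints, baseline, income = NULL,
                              manifest = NULL,
                              order = .CONSTRAINT_VARS,
                              empty_cells = c("drop", "error")) {
  empty_cells <- match.arg(empty_cells)
  for (v in c("age_sex", "household_type")) {
    if (!v %in% names(constraints)) stop("constraint '", v, "' is required")
  }
  zones <- names(baseline)
  n <- nrow(microdata)
  notes <- list()
  note <- function(zone, variable, action) {
    notes[[length(notes) + 1L]] <<- data.frame(zone_code = zone,
                                               variable = variable,
                                               action = action)
  }

  avail <- function(zone, var) {
    if (!is.null(manifest) && var %in% names(manifest)) {
      row <- manifest[manifest$zone_code == zone, var]
      if (length(row) && !isTRUE(as.logical(row[[1]]))) return(FALSE)
    }
    TRUE
  }

  # shared category index vectors for the tabular variables
  shared <- list()
  for (var in intersect(order, names(.MICRO_COL))) {
    if (!var %in% names(constraints)) next
    labels <- colnames(constraints[[var]])
    idx <- match(microdata[[.MICRO_COL[[var]]]], labels)
    if (anyNA(idx)) {
      stop("microdata ", .MICRO_COL[[var]], " labels not covered by the '",
           var, "' constraint categories")
    }
    shared[[var]] <- idx
  }

  zone_plan <- stats::setNames(vector("list", length(zones)), zones)
  for (z in zones) {
    entries <- list()
    for (var in order) {
      if (var == "income") {
        if (is.null(income)) next
        tz <- income$zone_targets[[z]]
        if (is.null(tz) || !avail(z, "income")) {
          note(z, "income", "dropped: unavailable")
          next
        }
        cats <- income_category(microdata$gross_weekly_wage,
                                microdata$employment_type,
                                income$boundaries[z, ])
        entry <- list(variable = "income", targets = tz,
                      cats = match(cats, names(tz)))
      } else {
        if (!var %in% names(constraints)) next
        tab <- constraints[[var]]
        if (!z %in% rownames(tab)) stop("zone ", z, " missing from '", var, "'")
        targets <- tab[z, ]
        if (!avail(z, var) || all(is.na(targets))) {
          if (var %in% c("age_sex", "household_type")) {
            stop("constraint '", var, "' unavailable for zone ", z,
                 " but is required")
          }
          note(z, var, "dropped: unavailable")
          next
        }
        cats <- shared[[var]]
        if (anyNA(targets)) {
          # merge missing categories into a present catch-all
          labels <- names(targets)
          present <- labels[!is.na(targets)]
          catch <- if ("other" %in% present) "other" else present[which.max(targets[present])]
          remap <- match(labels, labels)
          remap[is.na(targets)] <- match(catch, labels)
          cats <- remap[cats]
          keep <- !is.na(targets)
          targets <- targets[keep]
          targets <- targets * baseline[z] / sum(targets)
          cats <- match(labels[cats], names(targets))
          note(z, var, paste0("merged missing categories into '", catch, "'"))
        }
        entry <- list(variable = var, targets = targets, cats = cats)
      }
      entries[[length(entries) + 1L]] <- .resolve_empty_cells(entry, z,
                                                              baseline[z],
                                                              empty_cells, note)
    }
    zone_plan[[z]] <- entries
  }

  structure(list(zones = zones, ids = as.character(microdata$id),
                 zone = zone_plan,
                 order = order,
                 notes = if (length(notes)) do.call(rbind, notes) else
                   data.frame(zone_code = character(0), variable = character(0),
                              action = character(0))),
            class = "msim_plan")
}

# drop positive-target categories with no microdata mass, rescaling the
# remaining targets back to the zone baseline
.resolve_empty_cells <- function(entry, zone, base, mode, note) {
  counts <- tabulate(entry$cats, nbins = length(entry$targets))
  empty <- counts == 0 & entry$targets > 0
  if (!any(empty)) return(entry)
  if (mode == "error") {
    stop("empty cell(s) in '", entry$variable, "' for zone ", zone, ": ",
         paste(names(entry$targets)[empty], collapse = ", "))
  }
  warning("zone ", zone, " '", entry$variable, "': dropping empty categor",
          if (sum(empty) > 1) "ies " else "y ",
          paste(names(entry$targets)[empty], collapse = ", "),
          " and rescaling to baseline")
  note(zone, entry$variable,
       paste("dropped empty:", paste(names(entry$targets)[empty], collapse = ", ")))
  old <- names(entry$targets)
  keep <- !empty
  targets <- entry$targets[keep]
  targets <- targets * base / sum(targets)
  cats <- match(old[entry$cats], names(targets))  # NA for dropped cats
  list(variable = entry$variable, targets = targets, cats = cats)
}

#' @export
print.msim_plan <- function(x, ...) {
  nv <- lengths(x$zone)
  cat("Microsimulation fitting plan:", length(x$zones), "zones,",
      length(x$ids), "individuals\n")
  cat("Effective constraints per zone:", paste(range(nv), collapse = "-"), "\n")
  if (nrow(x$notes)) {
    cat("Adjustments:\n")
    print(x$notes, ...)
  } else cat("No per-zone adjustments were needed.\n")
  invisible(x)
}
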