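# Construction and scaling of the per-zone constraint tables that drive IPF.

#' Create a constraint table
#'
#' A constraint table holds, for one variable, the target count of people per
#' category in each zone. Internally it is a numeric matrix (zones x
#' categories) with the variable name attached; counts may be fractional
#' because every table is rescaled to a real-valued baseline population.
#'
#' @param counts Numeric matrix or data frame, zones in rows and categories in
#'   columns. A `zone_code` column (or row names) supplies the zone codes.
#' @param variable Constraint variable name, e.g. `"ethnicity"`.
#' @return A `constraint_table`: numeric matrix with zone codes as row names,
#'   category labels as column names and a `variable` attribute.
#' @export
constraint_table <- function(counts, variable) {
  if (is.data.frame(counts)) {
    if ("zone_code" %in% names(counts)) {
      zn <- as.character(counts$zone_code)
      counts <- counts[setdiff(names(counts), "zone_code")]
    } else {
      zn <- rownames(counts)
    }
    counts <- as.matrix(counts)
    rownames(counts) <- zn
  }
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("constraint counts need zone codes (rows) and category labels (columns)")
  }
  if (any(counts[!is.na(counts)] < 0)) stop("constraint counts must be >= 0")
  structure(counts, variable = variable,
            class = c("constraint_table", class(counts)))
}

#' @export
print.constraint_table <- function(x, ...) {
  cat("Constraint table:", attr(x, "variable"),
      sprintf("(%d zones x %d categories)\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Build the baseline population from mid-year and communal counts
#'
#' The baseline population of each zone is the household-resident count: the
#' mid-year population estimate minus residents of communal establishments
#' (care homes, halls of residence, ...), computed cellwise over the age-sex
#' cross-tabulation. Communal counts are typically available for a single
#' census year and held constant across study years. The resulting age-sex
#' table is itself the first (and defining) constraint: all other constraints
#' are scaled to its per-zone totals.
#'
#' @param midyear,communal `constraint_table`s (or coercible data frames) with
#'   identical zones and age-sex categories. `communal` defaults to zero.
#' @return List with `baseline` (named per-zone totals) and `constraint` (the
#'   age-sex household-resident table). Cells where communal exceeds mid-year
#'   are clamped to 0 with a warning, signalling inconsistent inputs.
#' @export
build_baseline <- function(midyear, communal = NULL) {
  midyear <- as_constraint(midyear, "age_sex")
  if (is.null(communal)) {
    communal <- midyear
    communal[] <- 0
  } else {
    communal <- as_constraint(communal, "age_sex")
    if (!identical(dimnames(midyear), dimnames(communal))) {
      stop("midyear and communal tables must share zones and categories")
    }
  }
  base <- unclass(midyear) - unclass(communal)
  if (any(base < 0)) {
    warning(sum(base < 0), " cell(s) with communal > midyear clamped to 0")
    base[base < 0] <- 0
  }
  tab <- constraint_table(base, attr(midyear, "variable"))
  totals <- rowSums(tab)
  if (any(totals <= 0)) stop("baseline population must be strictly positive per zone")
  list(baseline = totals, constraint = tab)
}

as_constraint <- function(x, variable) {
  if (inherits(x, "constraint_table")) x else constraint_table(x, variable)
}

#' Scale a raw constraint table to the baseline population
#'
#' Each zone's row is multiplied by `baseline[zone] / rowsum`, preserving the
#' category proportions exactly while forcing every constraint to share the
#' common per-zone total required by IPF. The operation is idempotent and
#' invariant to positive rescaling of the raw counts. `NA` cells (categories
#' unavailable for a zone) are ignored in the row sum and preserved; they are
#' resolved later by [harmonise_missing()].
#'
#' @param raw A `constraint_table` of raw counts.
#' @param baseline Named per-zone totals from [build_baseline()].
#' @return A scaled `constraint_table`. Zones whose raw row sum is zero are
#'   returned as all-`NA` rows and listed in the `unavailable_zones`
#'   attribute (the constraint is unusable there).
#' @export
scale_constraint <- function(raw, baseline) {
  raw <- as_constraint(raw, attr(raw, "variable"))
  zones <- rownames(raw)
  miss <- setdiff(zones, names(baseline))
  if (length(miss)) stop("zones missing from baseline: ", paste(miss, collapse = ", "))
  rs <- rowSums(raw, na.rm = TRUE)
  bad <- rs <= 0
  fac <- ifelse(bad, NA_real_, baseline[zones] / rs)
  out <- unclass(raw) * fac
  out[bad, ] <- NA_real_
  res <- constraint_table(out, attr(raw, "variable"))
  attr(res, "unavailable_zones") <- zones[bad]
  res
}

#' Build the income constraint from wage percentiles and employment counts
#'
#' Employee earnings arrive as per-zone gross-weekly-pay percentile boundaries
#' P10...P80. By construction of percentiles, each of the eight brackets
#' P0-P10 ... P70-P80 holds a tenth of the zone's employees and the open top
#' bracket P80-P100 holds a fifth. Self-employed and other (not in paid
#' employment) individuals fall outside the wage data and are appended as two
#' whole categories, giving eleven income categories which are then scaled to
#' the baseline. The same per-zone boundaries are later used to classify the
#' microdata zone by zone.
#'
#' Zones may have missing percentile boundaries (`NA`); adjacent brackets are
#' then merged at the missing boundary and their decile shares added, with the
#' merges recorded. Non-monotone boundaries mark the constraint unavailable
#' for that zone.
#'
#' @param boundaries Data frame or matrix with zone codes and columns
#'   `p10`...`p80` (weekly pounds).
#' @param employment Data frame or matrix with zone codes and columns
#'   `employees`, `self_employed`, `other` (counts).
#' @param baseline Named per-zone totals from [build_baseline()].
#' @return List with `zone_targets` (per-zone named vectors of scaled target
#'   counts over that zone's effective categories — the authoritative form
#'   consumed by IPF; `NULL` for unavailable zones), `prescale` (per-zone
#'   pre-scaling counts in the same layout), `constraint` (scaled
#'   `constraint_table` on the canonical eleven-category grid, `NA` where a
#'   zone uses merged brackets or is unavailable), `boundaries` (the per-zone
#'   boundary matrix) and `zone_categories` (per-zone effective labels).
#' @export
build_income_constraint <- function(boundaries, employment, baseline) {
  bmat <- .zone_matrix(boundaries, paste0("p", seq(10, 80, 10)))
  emat <- .zone_matrix(employment, c("employees", "self_employed", "other"))
  zones <- rownames(bmat)
  if (!setequal(zones, rownames(emat))) stop("boundary and employment zones differ")
  emat <- emat[zones, , drop = FALSE]
  miss <- setdiff(zones, names(baseline))
  if (length(miss)) stop("zones missing from baseline: ", paste(miss, collapse = ", "))

  full <- matrix(NA_real_, length(zones), length(.INCOME_LABELS),
                 dimnames = list(zones, .INCOME_LABELS))
  zone_targets <- prescale <- zone_categories <-
    stats::setNames(vector("list", length(zones)), zones)
  merged_zones <- bad_zones <- character(0)

  for (z in zones) {
    b <- bmat[z, ]
    ok <- !is.na(b)
    if (any(diff(b[ok]) <= 0)) {
      bad_zones <- c(bad_zones, z)
      next
    }
    # decile edges 0,10,...,80 surviving at available boundaries; each kept
    # bracket spans a whole number of deciles, the top always spans two.
    edge_idx <- which(c(TRUE, ok))             # edges P0 plus available P10..P80
    spans <- diff(c(edge_idx, 11L))            # in deciles; last is P80-P100
    lo <- (edge_idx - 1L) * 10L
    hi <- c(lo[-1L], 100L)
    labs <- paste0("P", lo, "_P", hi)
    if (length(labs) < 9L) merged_zones <- c(merged_zones, z)
    cats <- c(labs, "self_employed", "other")
    vals <- stats::setNames(
      c(emat[z, "employees"] * spans / 10,
        emat[z, "self_employed"], emat[z, "other"]), cats)
    zone_categories[[z]] <- cats
    prescale[[z]] <- vals
    zone_targets[[z]] <- vals * baseline[z] / sum(vals)
    known <- intersect(cats, .INCOME_LABELS)
    full[z, known] <- zone_targets[[z]][known]
  }

  if (length(bad_zones)) {
    warning("income constraint unavailable (non-monotone boundaries) for: ",
            paste(bad_zones, collapse = ", "))
  }
  if (length(merged_zones)) {
    message("income brackets merged at missing boundaries for ",
            length(merged_zones), " zone(s)")
  }
  list(zone_targets = zone_targets, prescale = prescale,
       constraint = constraint_table(full, "income"),
       boundaries = bmat, zone_categories = zone_categories)
}

.zone_matrix <- function(x, cols) {
  if (is.data.frame(x)) {
    zn <- as.character(x$zone_code)
    x <- as.matrix(x[setdiff(names(x), "zone_code")])
    rownames(x) <- zn
  }
  nm <- tolower(colnames(x))
  miss <- setdiff(cols, nm)
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  colnames(x) <- nm
  storage.mode(x) <- "double"
  x[, cols, drop = FALSE]
}

#' Classify wages into a zone's income categories
#'
#' Employees are placed in the bracket whose boundaries straddle their gross
#' weekly wage (left-closed: a wage equal to a boundary opens the next
#' bracket); self-employed and other individuals go to their own categories
#' regardless of wage, mirroring the constraint construction.
#'
#' @param wage Numeric vector of gross weekly wages.
#' @param employment_type Character vector (`Employee`/`Self-employed`/`Other`).
#' @param boundaries Numeric vector of the zone's available P10...P80
#'   boundaries (strictly increasing, `NA`s allowed and skipped).
#' @return Character vector of income category labels for that zone.
#' @export
income_category <- function(wage, employment_type, boundaries) {
  b <- boundaries[!is.na(boundaries)]
  edge_idx <- which(c(TRUE, !is.na(boundaries)))
  lo <- (edge_idx - 1L) * 10L
  hi <- c(lo[-1L], 100L)
  labs <- paste0("P", lo, "_P", hi)
  out <- character(length(wage))
  emp <- employment_type == "Employee"
  out[employment_type == "Self-employed"] <- "self_employed"
  out[employment_type == "Other"] <- "other"
  out[emp] <- labs[findInterval(wage[emp], b) + 1L]
  out
}

#' Audit constraint availability
#'
#' Summarises an availability manifest into the number of zones with each
#' constraint variable available, optionally per year — the standard audit
#' view for a multi-year run.
#'
#' @param manifest Data frame with `zone_code`, optional `year`, and one
#'   logical column per constraint variable.
#' @return Data frame of zone counts per variable (rows are years when a
#'   `year` column is present).
#' @export
audit_constraints <- function(manifest) {
  vars <- intersect(.CONSTRAINT_VARS, names(manifest))
  if (!length(vars)) stop("manifest has no constraint variable columns")
  f <- function(df) vapply(df[vars], function(v) sum(as.logical(v)), integer(1))
  if ("year" %in% names(manifest)) {
    out <- do.call(rbind, lapply(split(manifest, manifest$year), f))
    data.frame(year = as.integer(rownames(out)), out, row.names = NULL)
  } else {
    as.data.frame(as.list(f(manifest)))
  }
}
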