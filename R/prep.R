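# Formatting raw survey microdata into the common categorical classes used by
# the constraint tables.

#' Assign an age-sex class
#'
#' Maps age in whole years and sex to one of the twenty age-sex labels: twelve
#' adult classes (16-24, 25-34, 35-49, 50-64, 65-74, 75+ by sex) and four
#' child classes (0-9 and 10-15 by sex). Bin edges are closed on both sides as
#' printed ("25-34" means 25 <= age <= 34); the top bin is open-ended. Ages 15
#' and under route to the child model.
#'
#' @param age Numeric vector of ages in years (0-130).
#' @param sex Character vector, `"F"`/`"M"` (also accepts
#'   `"female"`/`"male"`, case-insensitive).
#' @return Character vector of labels such as `"M_50_64"` or `"F_0_9"`.
#' @examples
#' categorise_age_sex(c(57, 3), c("M", "F"))
#' @export
categorise_age_sex <- function(age, sex) {
  if (length(sex) == 1L) sex <- rep(sex, length(age))
  if (length(age) != length(sex)) stop("age and sex must have equal length")
  if (any(!is.finite(age)) || any(age < 0) || any(age > 130)) {
    stop("ages must be finite and within [0, 130]")
  }
  s <- toupper(substr(as.character(sex), 1, 1))
  if (!all(s %in% c("F", "M"))) stop("sex must be 'F'/'M' (or female/male)")
  breaks <- c(0, 10, 16, 25, 35, 50, 65, 75, Inf)
  bands <- c(.AGE_BANDS_CHILD, .AGE_BANDS_ADULT)
  band <- bands[findInterval(age, breaks)]
  paste(s, band, sep = "_")
}

#' Split a microdata pool into adult and child sub-pools
#'
#' The adult model (ages 16 and over) and the child model (15 and under) are
#' fitted separately; the split is driven entirely by the assigned age-sex
#' label so it stays consistent with the constraint tables.
#'
#' @param individuals Data frame with an `age_sex` column.
#' @return List with elements `adults` and `children`, a disjoint exhaustive
#'   partition of the input rows.
#' @export
split_adult_child <- function(individuals) {
  if (!"age_sex" %in% names(individuals)) stop("individuals must carry age_sex")
  lab <- individuals$age_sex
  unknown <- setdiff(unique(lab), c(.AGE_SEX_ADULT, .AGE_SEX_CHILD))
  if (length(unknown)) stop("unknown age_sex labels: ", paste(unknown, collapse = ", "))
  is_child <- lab %in% .AGE_SEX_CHILD
  list(adults = individuals[!is_child, , drop = FALSE],
       children = individuals[is_child, , drop = FALSE])
}

#' Restrict survey records to a calendar year
#'
#' Survey releases may span financial years (April to March); the analysis
#' uses calendar years throughout, removing out-of-year records and appending
#' in-year records from adjacent releases. Feed the union of the releases that
#' overlap the target year and this returns the calendar-year subset.
#'
#' @param records Data frame carrying a survey completion date column.
#' @param year Target calendar year.
#' @param date_col Name of the date column (coerced with [as.Date()]).
#' @return The rows of `records` dated within Jan 1 - Dec 31 of `year`.
#'   Records with missing dates are dropped with a warning giving the count.
#' @export
filter_calendar_year <- function(records, year, date_col = "survey_date") {
  if (!date_col %in% names(records)) stop("no such date column: ", date_col)
  d <- as.Date(records[[date_col]])
  miss <- is.na(d)
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing survey date dropped")
  }
  keep <- !miss & d >= as.Date(sprintf("%d-01-01", year)) &
    d <= as.Date(sprintf("%d-12-31", year))
  records[keep, , drop = FALSE]
}

#' Validate and normalise formatted microdata
#'
#' Checks that a formatted microdata table uses only the canonical category
#' labels, that ids are unique and wages nonnegative. Unknown ethnicity
#' strings are mapped to the catch-all `"other"` with a warning; anything else
#' out of vocabulary is an error.
#'
#' @param microdata Data frame with columns `id`, `region`, `age_sex`,
#'   `ethnicity`, `student`, `unemployed`, `gross_weekly_wage`,
#'   `employment_type`, `household_type`.
#' @return The validated (possibly re-labelled) microdata.
#' @export
validate_microdata <- function(microdata) {
  need <- c("id", "region", "age_sex", "ethnicity", "student", "unemployed",
            "gross_weekly_wage", "employment_type", "household_type")
  miss <- setdiff(need, names(microdata))
  if (length(miss)) stop("microdata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(microdata$id)) stop("microdata ids are not unique")
  w <- microdata$gross_weekly_wage
  if (any(!is.finite(w)) || any(w < 0)) stop("wages must be finite and >= 0")

  bad_eth <- !microdata$ethnicity %in% .ETHNICITY
  if (any(bad_eth)) {
    warning(sum(bad_eth), " unknown ethnicity label(s) mapped to 'other'")
    microdata$ethnicity[bad_eth] <- "other"
  }
  chk <- list(region = .REGIONS, age_sex = c(.AGE_SEX_ADULT, .AGE_SEX_CHILD),
              student = .STUDENT, unemployed = .UNEMPLOYED,
              employment_type = .EMPLOYMENT_TYPE)
  for (v in names(chk)) {
    # household_type checked only for adults below
    bad <- setdiff(unique(microdata[[v]]), chk[[v]])
    if (length(bad)) stop("invalid ", v, " label(s): ", paste(bad, collapse = ", "))
  }
  adult <- microdata$age_sex %in% .AGE_SEX_ADULT
  bad_hh <- setdiff(unique(microdata$household_type[adult]), .HOUSEHOLD_TYPE)
  if (length(bad_hh)) stop("invalid household_type label(s): ", paste(bad_hh, collapse = ", "))
  microdata
}
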