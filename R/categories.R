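#' @keywords internal
"_PACKAGE"

# Canonical category labels shared by the microdata, the constraint tables and
# the synthetic-world generator.  IPF requires bit-identical labels on both
# sides, so every module routes through these vectors.

.REGIONS <- c(
  "South East", "London", "Scotland", "Wales", "Northern Ireland",
  "West Midlands", "South West", "North East", "North West",
  "Eastern", "East Midlands", "Yorkshire"
)
.GB_REGIONS <- setdiff(.REGIONS, "Northern Ireland")

.AGE_BANDS_ADULT <- c("16_24", "25_34", "35_49", "50_64", "65_74", "75_pl")
.AGE_BANDS_CHILD <- c("0_9", "10_15")

.AGE_SEX_ADULT <- as.vector(outer(c("F", "M"), .AGE_BANDS_ADULT, paste, sep = "_"))
.AGE_SEX_CHILD <- as.vector(outer(c("F", "M"), .AGE_BANDS_CHILD, paste, sep = "_"))

.ETHNICITY <- c("white", "mixed", "black", "other")
.STUDENT <- c("student", "not-student")
.UNEMPLOYED <- c("unemployed", "not-unemployed")
.EMPLOYMENT_TYPE <- c("Employee", "Self-employed", "Other")

# Household life-stage classes: grouped age of the individual followed by the
# presence/age of dependent children (and single- vs multi-person household in
# the older groups).
.HOUSEHOLD_TYPE <- c(
  "16_24_dep_n", "16_24_dep_y",
  "25_34_dep_n", "25_34_dep_y_0_4", "25_34_dep_y_5_10", "25_34_dep_y_11_pl",
  "35_54_dep_n", "35_54_dep_y_0_4", "35_54_dep_y_5_10", "35_54_dep_y_11_pl",
  "55_64_mph_dep_n", "55_64_sph", "55_74_dep_y",
  "65_74_mph_dep_n", "65_74_sph",
  "75_pl_mph", "75_pl_sph"
)

.INCOME_DECILES <- paste0("P", seq(0, 70, 10), "_P", seq(10, 80, 10))
.INCOME_LABELS <- c(.INCOME_DECILES, "P80_P100", "self_employed", "other")

.CONSTRAINT_VARS <- c("age_sex", "household_type", "ethnicity", "student",
                      "unemployment", "income")

.PRICE_CATEGORIES <- c("food_nonalcoholic", "alcohol_tobacco", "restaurants_hotels")

#' Category levels for a microsimulation variable
#'
#' Returns the canonical category labels used throughout the package for one
#' of the constraint/microdata variables. Constraint tables, microdata columns
#' and the synthetic generator all share these labels, which is a hard
#' requirement of IPF (targets and microdata must be classified identically).
#'
#' @param variable One of `"region"`, `"age_sex"` (adult), `"age_sex_child"`,
#'   `"ethnicity"`, `"student"`, `"unemployment"`, `"employment_type"`,
#'   `"household_type"`, `"income"`.
#' @return Character vector of category labels.
#' @examples
#' category_levels("ethnicity")
#' @export
category_levels <- function(variable) {
  switch(variable,
    region = .REGIONS,
    age_sex = .AGE_SEX_ADULT,
    age_sex_child = .AGE_SEX_CHILD,
    ethnicity = .ETHNICITY,
    student = .STUDENT,
    unemployment = .UNEMPLOYED,
    employment_type = .EMPLOYMENT_TYPE,
    household_type = .HOUSEHOLD_TYPE,
    income = .INCOME_LABELS,
    stop("unknown variable: ", variable)
  )
}
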