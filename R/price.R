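# Relative regional consumer price level (RRCPL) adjustment.
#
# Reweighting can assign a survey respondent from any region to any zone, but
# goods cost different amounts in different regions. Diary values are scaled
# to a UK-average price (UK = 100) and back to the destination region's
# level: amount * (index_dest / index_source). Detailed per-category indices
# exist for London, Scotland, Wales and Northern Ireland; other regions carry
# one aggregate index repeated across the three price categories.

#' Load an RRCPL table
#'
#' Two vintages are shipped: the 2016 table with published regional indices,
#' and a synthetic 2010 stand-in (the 2010 release is not redistributable
#' here; the shipped values are constructed and labelled synthetic). Region
#' names follow the microdata region labels.
#'
#' @param vintage 2010 or 2016, or a path to a CSV with columns
#'   `vintage, region, price_category, index, detail_flag`.
#' @return Data frame of class `rrcpl`.
#' @export
rrcpl_table <- function(vintage = 2016) {
  path <- if (is.character(vintage) && file.exists(vintage)) {
    vintage
  } else if (as.integer(vintage) == 2016L) {
    system.file("extdata", "rrcpl_2016.csv", package = "microspend",
                mustWork = TRUE)
  } else if (as.integer(vintage) == 2010L) {
    system.file("extdata", "rrcpl_2010_synthetic.csv", package = "microspend",
                mustWork = TRUE)
  } else stop("no RRCPL table for vintage ", vintage)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vintage", "region", "price_category", "index", "detail_flag")
  if (!all(need %in% names(tab))) stop("RRCPL table missing columns")
  if (any(tab$index <= 0)) stop("RRCPL indices must be > 0")
  class(tab) <- c("rrcpl", "data.frame")
  tab
}

#' Select the RRCPL vintage applicable to a study year
#'
#' Price levels are not published annually; the closest available vintage is
#' used: the 2010 table for years 2008-2012 and the 2016 table for 2013
#' onwards.
#'
#' @param year Study year, 2008-2016.
#' @return An `rrcpl` table.
#' @export
select_vintage <- function(year) {
  if (year < 2008 || year > 2016) stop("year out of range 2008-2016: ", year)
  rrcpl_table(if (year <= 2012) 2010 else 2016)
}

#' Map a COICOP code to its price category
#'
#' Prices are indexed for three broad groups only: COICOP division 1 (food
#' and non-alcoholic beverages), division 2 (alcohol and tobacco) and the
#' catering division 11 (restaurants and hotels, covering food and drink
#' consumed away from home). The division is the first dotted component of
#' the code. An editable lookup overrides the rule for individual codes.
#'
#' @param coicop Character vector of dotted COICOP codes.
#' @param lookup Optional data frame (`coicop`, `price_category`) consulted
#'   before the division rule.
#' @return Character vector over
#'   `c("food_nonalcoholic", "alcohol_tobacco", "restaurants_hotels")`.
#'   Unknown divisions raise an error listing the offending codes.
#' @examples
#' price_category(c("1.1.6.2.1", "2.2.1.1.1", "11.1.1.1.1"))
#' @export
price_category <- function(coicop, lookup = NULL) {
  out <- rep(NA_character_, length(coicop))
  if (!is.null(lookup)) {
    m <- match(coicop, lookup$coicop)
    out[!is.na(m)] <- lookup$price_category[m[!is.na(m)]]
  }
  division <- sub("\\..*$", "", coicop)
  rule <- c("1" = "food_nonalcoholic", "2" = "alcohol_tobacco",
            "11" = "restaurants_hotels")
  todo <- is.na(out)
  out[todo] <- rule[division[todo]]
  if (anyNA(out)) {
    stop("COICOP code(s) with no price category: ",
         paste(unique(coicop[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Adjust expenditure between regional price levels
#'
#' Rescales an amount recorded at the source region's price level to the
#' destination region's level via the UK average:
#' `amount * (index_dest / 100) / (index_source / 100)`. The detailed
#' category index is used where the region has one; aggregate-index regions
#' carry the same value for every category, so the formula is uniform. The
#' adjustment is exact for round trips and multiplicative across chained
#' regions.
#'
#' @param amount Nonnegative amounts in pounds (vectorised).
#' @param source_region,dest_region Region labels present in `table`
#'   (vectorised, recycled).
#' @param category Price category label(s).
#' @param table An `rrcpl` table from [rrcpl_table()] or [select_vintage()].
#' @return Adjusted amounts in pounds.
#' @examples
#' adjust_expenditure(10, "Scotland", "London", "food_nonalcoholic",
#'                    rrcpl_table(2016))
#' @export
adjust_expenditure <- function(amount, source_region, dest_region, category,
                               table) {
  if (any(amount < 0)) stop("amounts must be >= 0")
  src <- rrcpl_index(table, source_region, category)
  dst <- rrcpl_index(table, dest_region, category)
  amount * dst / src
}

#' Look up RRCPL indices
#'
#' @param table An `rrcpl` table.
#' @param region,category Label vectors (recycled against each other).
#' @return Numeric index values (UK = 100).
#' @export
rrcpl_index <- function(table, region, category) {
  key <- paste(region, category, sep = "\r")
  tk <- paste(table$region, table$price_category, sep = "\r")
  m <- match(key, tk)
  if (anyNA(m)) {
    bad <- unique(paste0(region, "/", category)[is.na(m)])
    stop("no RRCPL index for: ", paste(bad, collapse = ", "))
  }
  table$index[m]
}
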