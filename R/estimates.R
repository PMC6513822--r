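# Zone-level expenditure estimates: weights x price-adjusted diary.

#' Weighted zone totals of price-adjusted expenditure
#'
#' For every zone and commodity category, sums each individual's weekly diary
#' expenditure — adjusted from the individual's source region to the zone's
#' region at the category's price level — weighted by the fitted
#' individual-to-zone weight:
#' `total[z, c] = sum_i w[i, z] * adjust(exp[i, c], region_i -> region_z)`.
#' Individuals without a diary record for a category contribute zero.
#'
#' @param fit An `msim_fit`, or a weights matrix (individuals x zones with
#'   dimnames).
#' @param diary Data frame with `id`, `coicop`, `weekly_expenditure`.
#' @param microdata Data frame with `id` and `region` covering every
#'   individual in the weights (an error otherwise).
#' @param region_of_zone Named character vector, zone code -> region label.
#' @param rrcpl An `rrcpl` table (defaults to the 2016 vintage).
#' @param lookup Optional COICOP -> price-category lookup data frame.
#' @return Zones x COICOP-categories matrix of total weekly pounds.
#' @export
zone_expenditure <- function(fit, diary, microdata, region_of_zone,
                             rrcpl = rrcpl_table(2016), lookup = NULL) {
  W <- if (inherits(fit, "msim_fit")) fit$weights else fit
  ids <- rownames(W)
  zones <- colnames(W)
  m <- match(ids, as.character(microdata$id))
  if (anyNA(m)) stop("individuals in weights absent from microdata: ",
                     paste(utils::head(ids[is.na(m)]), collapse = ", "))
  src_region <- microdata$region[m]
  miss_z <- setdiff(zones, names(region_of_zone))
  if (length(miss_z)) stop("zones without a region: ", paste(miss_z, collapse = ", "))

  keep <- diary$id %in% ids
  diary <- diary[keep, , drop = FALSE]
  codes <- sort(unique(as.character(diary$coicop)))
  pc <- price_category(codes, lookup)

  # amounts at UK-average price level: divide by the source-region index
  A <- matrix(0, length(ids), length(codes), dimnames = list(ids, codes))
  ri <- match(as.character(diary$id), ids)
  ci <- match(as.character(diary$coicop), codes)
  src_idx <- rrcpl_index(rrcpl, src_region[ri], pc[ci])
  vals <- diary$weekly_expenditure * 100 / src_idx
  key <- paste(ri, ci)
  if (anyDuplicated(key)) {          # tolerate split diary records: sum them
    vals <- rowsum(vals, key, reorder = FALSE)
    kk <- matrix(as.integer(unlist(strsplit(rownames(vals), " ", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
    A[kk] <- vals
  } else {
    A[cbind(ri, ci)] <- vals
  }

  totals <- crossprod(W, A)                       # zones x codes, UK prices
  dest_idx <- vapply(seq_along(codes), function(j)
    rrcpl_index(rrcpl, region_of_zone[zones], pc[j]),
    numeric(length(zones)))
  totals * matrix(dest_idx, nrow = length(zones)) / 100
}

#' Merge adult and child totals into per-capita estimates
#'
#' Combines the adult- and child-model zone totals and divides by the full
#' household-resident population, yielding average weekly expenditure per
#' person (all residents):
#' `mean[z, c] = (adult_total + child_total) / (adult_pop + child_pop)`.
#'
#' @param adult_totals Zones x categories matrix from [zone_expenditure()].
#' @param child_totals Optional matrix on the same zones (child diaries are
#'   commonly absent — children contribute a negligible share of spend — in
#'   which case they enter as zero).
#' @param adult_pop,child_pop Named per-zone baseline populations.
#' @return Long data frame: `zone_code`, `coicop`,
#'   `mean_weekly_expenditure_gbp`, of class `expenditure_estimate`.
#' @export
merge_per_capita <- function(adult_totals, child_totals = NULL,
                             adult_pop, child_pop = NULL) {
  zones <- rownames(adult_totals)
  if (is.null(child_pop)) child_pop <- stats::setNames(rep(0, length(zones)), zones)
  if (is.null(child_totals)) {
    child_totals <- adult_totals
    child_totals[] <- 0
  }
  if (!identical(rownames(child_totals), zones)) {
    stop("adult and child totals must cover the same zones in order")
  }
  pop <- adult_pop[zones] + child_pop[zones]
  if (any(!is.finite(pop)) || any(pop <= 0)) {
    stop("combined population must be positive for every zone")
  }
  mean_mat <- (adult_totals + child_totals) / pop
  out <- data.frame(
    zone_code = rep(zones, times = ncol(mean_mat)),
    coicop = rep(colnames(mean_mat), each = length(zones)),
    mean_weekly_expenditure_gbp = as.vector(mean_mat),
    stringsAsFactors = FALSE
  )
  class(out) <- c("expenditure_estimate", "data.frame")
  out
}

#' Aggregate estimates over COICOP code groups
#'
#' COICOP is hierarchical, so higher-level categories are exact sums of their
#' members: an aggregate for prefix `"1.1.2"` sums every code whose leading
#' dotted components are `1.1.2` (including the code itself). Groups may also
#' be given as explicit code vectors.
#'
#' @param estimates An `expenditure_estimate` (long form).
#' @param groups Named list; each element is a character vector of dotted
#'   prefixes and/or full codes defining one aggregate.
#' @return `expenditure_estimate` with one row per zone per group label.
#'   A group matching no codes is an error.
#' @examples
#' # groups <- list(all_food_and_drink = c("1", "11"), tobacco = "2.2")
#' @export
aggregate_categories <- function(estimates, groups) {
  codes <- unique(estimates$coicop)
  out <- lapply(names(groups), function(g) {
    member <- codes[.matches_prefix(codes, groups[[g]])]
    if (!length(member)) stop("no codes match group '", g, "'")
    sub <- estimates[estimates$coicop %in% member, , drop = FALSE]
    agg <- rowsum(sub$mean_weekly_expenditure_gbp, sub$zone_code, reorder = TRUE)
    data.frame(zone_code = rownames(agg), coicop = g,
               mean_weekly_expenditure_gbp = agg[, 1], stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  class(out) <- c("expenditure_estimate", "data.frame")
  out
}

.matches_prefix <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) {
    hit <- hit | codes == p | startsWith(codes, paste0(p, "."))
  }
  hit
}

#' Standard aggregate category groups
#'
#' The customary cumulative categories: all food and drink, alcoholic drinks,
#' tobacco and cigarettes, fruit and vegetables, and all products.
#'
#' @return Named list of prefix vectors for [aggregate_categories()].
#' @export
standard_aggregates <- function() {
  list(
    all_food_and_drink = c("1", "11"),
    alcoholic_drinks = "2.1",
    tobacco_and_cigarettes = "2.2",
    fruit_and_vegetables = c("1.1.6", "1.1.7"),
    all_products = c("1", "2", "11")
  )
}
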