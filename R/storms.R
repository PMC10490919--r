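#' Sample a synthetic tropical-cyclone catalog
#'
#' Draws a catalog of landfalling tropical cyclones with a fixed severity
#' mix: six tropical storms (category 0), two Category-1, one Category-2,
#' one Category-3, and two Category-4 hurricanes -- twelve storms in all,
#' the mix observed on the Louisiana coast over 2015--2021. Landfall dates
#' fall in the June--November season, each storm impacts one region, and
#' storms impacting the same region are separated by at least `min_gap_days`
#' so their five-week recovery windows do not overlap. The category multiset
#' is fixed; only dates and regions vary with the seed.
#'
#' @param seed Integer seed.
#' @param years Candidate landfall years.
#' @param categories Integer vector of storm categories (0 = tropical storm,
#'   1--5 = Saffir--Simpson hurricane category); the default is the fixed
#'   12-storm mix.
#' @param regions Regions storms may impact.
#' @param min_gap_days Minimum separation between landfalls in one region.
#' @return A data frame of class `"storm_catalog"`, sorted by landfall date,
#'   with columns `storm_id`, `name`, `landfall_date`, `category`,
#'   `impacted_region`.
#' @examples
#' storms <- sample_storm_catalog(seed = 1)
#' table(storms$category)
#' @export
sample_storm_catalog <- function(seed = 1,
                                 years = 2015:2021,
                                 categories = c(rep(0L, 6), 1L, 1L, 2L, 3L, 4L, 4L),
                                 regions = c("east", "west"),
                                 min_gap_days = 42) {
  stopifnot(all(categories %in% 0:5))
  set.seed(seed)
  n <- length(categories)
  for (attempt in 1:500) {
    yr <- years[sample.int(length(years), n, replace = TRUE)]
    # landfalls concentrate in the Aug-Oct heart of the season
    month <- sample(6:11, n, replace = TRUE,
                    prob = c(0.08, 0.12, 0.25, 0.30, 0.18, 0.07))
    day <- sample(1:28, n, replace = TRUE)
    date <- as.Date(sprintf("%d-%02d-%02d", yr, month, day))
    region <- regions[sample.int(length(regions), n, replace = TRUE)]
    ok <- TRUE
    for (rg in regions) {
      d <- sort(date[region == rg])
      if (length(d) > 1 && any(diff(as.numeric(d)) < min_gap_days)) ok <- FALSE
    }
    if (anyDuplicated(date)) ok <- FALSE
    if (ok) break
  }
  if (!ok) stop("could not place storms with the requested separation")
  ord <- order(date)
  out <- data.frame(
    storm_id = sprintf("S%02d", seq_len(n)),
    name = sprintf("Storm-%s", LETTERS[seq_len(n)]),
    landfall_date = date[ord],
    category = as.integer(categories[ord]),
    impacted_region = region[ord]
  )
  class(out) <- c("storm_catalog", "data.frame")
  out
}

#' Impact week of a storm
#'
#' The first survey week in which a storm disrupts effort. Tropical-storm and
#' hurricane warnings are issued with roughly 36 hours of lead time, so when
#' landfall falls early in a week (Monday or Tuesday) the warning -- and the
#' collapse in effort -- belongs to the preceding week; the impact window
#' then starts at the warning week. Otherwise it starts at the landfall week.
#'
#' @param landfall_date `Date` vector of landfalls.
#' @param calendar Survey calendar from [make_calendar()].
#' @param warning_lead_days Days of warning lead time before landfall.
#' @return Integer row indices into `calendar`.
#' @export
storm_impact_week <- function(landfall_date, calendar, warning_lead_days = 2) {
  week_of_date(as.Date(landfall_date) - warning_lead_days, calendar)
}

#' Derive weekly tropical-storm and hurricane warning counts from a catalog
#'
#' Each storm generates warnings across the region's forecast zones in its
#' warning week (the week containing the 36-hour-lead warning issuance, which
#' precedes the landfall week when landfall falls on a Monday or Tuesday).
#' Tropical storms draw tropical-storm warnings only; hurricanes draw both.
#'
#' @param storms A storm catalog from [sample_storm_catalog()].
#' @param calendar Survey calendar.
#' @param zones_per_region Named integer vector of forecast zones per region.
#' @param warning_lead_days Days of warning lead time before landfall.
#' @return Data frame `year`, `week`, `region`, `ts_warn_count`,
#'   `hu_warn_count` with one row per storm warning week.
#' @export
storm_warning_counts <- function(storms, calendar,
                                 zones_per_region = c(east = 7, west = 4),
                                 warning_lead_days = 2) {
  idx <- storm_impact_week(storms$landfall_date, calendar, warning_lead_days)
  if (anyNA(idx)) stop("storm warning week outside the calendar")
  zones <- zones_per_region[storms$impacted_region]
  data.frame(
    year = calendar$year[idx],
    week = calendar$week[idx],
    region = storms$impacted_region,
    ts_warn_count = as.integer(2 * zones),
    hu_warn_count = as.integer(ifelse(storms$category >= 1, 2 * zones, 0))
  )
}
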