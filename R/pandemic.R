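#' Monthly effort totals for one region-year
#'
#' Rolls weekly effort up to months using the majority-day month labels of
#' the survey calendar, so the twelve totals partition the year's 52 weeks
#' exactly and sum to the annual total.
#'
#' @param effort Regional weekly effort table.
#' @param calendar Survey calendar.
#' @param region Region identifier.
#' @param year Year to roll up.
#' @return Data frame `month` (1--12), `total`.
#' @export
monthly_totals <- function(effort, calendar, region, year) {
  cal <- calendar[calendar$year == year, ]
  if (nrow(cal) != 52) stop("calendar does not cover year ", year)
  e <- effort[effort$region == region & effort$year == year, ]
  pos <- match(cal$week, e$week)
  if (anyNA(pos)) {
    stop("missing effort weeks for ", region, " ", year, ": ",
         paste(cal$week[is.na(pos)], collapse = ", "))
  }
  tot <- tapply(e$effort[pos], factor(cal$month, levels = 1:12), sum,
                default = 0)
  data.frame(month = 1:12, total = as.numeric(tot))
}

#' Pandemic-year effort as a percentage of normal
#'
#' Compares monthly 2020 effort against the 2015--2019 baseline for one
#' region. The baseline center is the arithmetic mean across the five
#' pre-pandemic years (configurable to the median) and the envelope is their
#' min/max range. Both the percent difference from baseline
#' (`100 * (E2020 - baseline) / baseline`, "X% higher") and the
#' percent-of-normal ratio (`100 * E2020 / baseline`) are reported.
#'
#' @param effort Regional weekly effort covering 2015--2020.
#' @param calendar Survey calendar covering the same years.
#' @param region Region identifier.
#' @param pandemic_year Comparison year (2020).
#' @param baseline_years Baseline years (2015--2019; all must be present).
#' @param center Baseline center: `"mean"` or `"median"`.
#' @return Data frame with one row per month: `region`, `month`,
#'   `effort_2020`, `baseline_mean`, `baseline_min`, `baseline_max`,
#'   `pct_diff`, `pct_of_normal`.
#' @export
percent_of_normal <- function(effort, calendar, region,
                              pandemic_year = 2020,
                              baseline_years = 2015:2019,
                              center = c("mean", "median")) {
  center <- match.arg(center)
  cfun <- if (center == "mean") mean else stats::median
  base <- sapply(baseline_years, function(yr) {
    monthly_totals(effort, calendar, region, yr)$total
  })
  e2020 <- monthly_totals(effort, calendar, region, pandemic_year)$total
  bmean <- apply(base, 1, cfun)
  if (any(bmean == 0)) {
    stop("baseline ", center, " effort is zero in month(s) ",
         paste(which(bmean == 0), collapse = ", "),
         ": percentage undefined")
  }
  data.frame(region = region, month = 1:12,
             effort_2020 = e2020,
             baseline_mean = bmean,
             baseline_min = apply(base, 1, min),
             baseline_max = apply(base, 1, max),
             pct_diff = 100 * (e2020 - bmean) / bmean,
             pct_of_normal = 100 * e2020 / bmean)
}

#' Two-region pandemic summary
#'
#' [percent_of_normal()] for each region, stacked: 24 rows for the default
#' two-region system.
#'
#' @param effort Weekly effort table for all regions.
#' @param calendar Survey calendar.
#' @param regions Regions to summarize.
#' @param ... Passed to [percent_of_normal()].
#' @return Data frame of stacked per-region monthly summaries.
#' @export
pandemic_summary <- function(effort, calendar, regions = c("east", "west"),
                             ...) {
  out <- do.call(rbind, lapply(regions, function(rg) {
    percent_of_normal(effort, calendar, rg, ...)
  }))
  rownames(out) <- NULL
  out
}
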