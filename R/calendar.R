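#' Build the Monday-start survey calendar
#'
#' Weekly creel estimates are indexed by survey weeks that start on Monday and
#' end the following Sunday, with exactly 52 weeks per year. Week 1 of a year
#' starts on the first Monday on or after January 1; in years where a 53rd
#' (partial or full) week would fit, it is dropped so that every year
#' contributes exactly 52 weeks.
#'
#' Each week is labelled with the calendar month containing at least 4 of its
#' 7 days (a majority; ties are impossible with a 7-day week), and flagged if
#' its span contains Memorial Day (last Monday of May), Independence Day
#' (July 4), or Labor Day (first Monday of September).
#'
#' @param start_year,end_year First and last year of the calendar (inclusive).
#' @return A data frame with one row per week and columns `year`, `week`
#'   (1--52), `monday` (`Date` of the first day), `month` (majority-rule month
#'   label, 1--12), and `holiday_week` (logical).
#' @examples
#' cal <- make_calendar(2015, 2021)
#' nrow(cal) # 364
#' @export
make_calendar <- function(start_year, end_year) {
  stopifnot(length(start_year) == 1L, length(end_year) == 1L,
            is.finite(start_year), is.finite(end_year))
  if (start_year != round(start_year) || end_year != round(end_year)) {
    stop("`start_year` and `end_year` must be whole years")
  }
  if (start_year > end_year) {
    stop("`start_year` must not exceed `end_year`")
  }
  rows <- lapply(seq.int(start_year, end_year), function(yr) {
    jan1 <- as.Date(sprintf("%d-01-01", yr))
    # POSIXlt wday: 0 = Sunday, 1 = Monday, ...
    offset <- (8L - as.POSIXlt(jan1)$wday) %% 7L
    data.frame(
      year = yr,
      week = 1:52,
      monday = jan1 + offset + 7 * (0:51)
    )
  })
  cal <- do.call(rbind, rows)
  cal$month <- week_month_label(cal$monday)
  cal$holiday_week <- week_has_holiday(cal$monday)
  cal
}

#' Majority-rule month label for Monday-start weeks
#'
#' A week spanning two months takes the label of the month holding at least 4
#' of its 7 days.
#'
#' @param monday `Date` vector of week start days (Mondays).
#' @return Integer month labels (1--12).
#' @export
week_month_label <- function(monday) {
  vapply(as.Date(monday), function(m) {
    months <- as.POSIXlt(m + 0:6)$mon + 1L
    tab <- table(months)
    as.integer(names(tab)[tab >= 4L][1L])
  }, integer(1))
}

#' Federal summer-holiday dates for a year
#'
#' Memorial Day (last Monday of May), Independence Day (July 4), and Labor Day
#' (first Monday of September): the three long warm-weather weekends with a
#' well-known effort surge, excluded from the weather analysis.
#'
#' @param year Integer year.
#' @return A `Date` vector of length 3, named.
#' @export
holiday_dates <- function(year) {
  may31 <- as.Date(sprintf("%d-05-31", year))
  memorial <- may31 - (as.POSIXlt(may31)$wday - 1L) %% 7L
  sep1 <- as.Date(sprintf("%d-09-01", year))
  labor <- sep1 + (8L - as.POSIXlt(sep1)$wday) %% 7L
  out <- c(memorial, as.Date(sprintf("%d-07-04", year)), labor)
  names(out) <- c("memorial", "independence", "labor")
  out
}

week_has_holiday <- function(monday) {
  vapply(as.Date(monday), function(m) {
    span <- m + 0:6
    yrs <- unique(as.POSIXlt(span)$year + 1900L)
    hol <- do.call(c, lapply(yrs, holiday_dates))
    any(span %in% hol)
  }, logical(1))
}

#' Locate the survey week containing a date
#'
#' @param date `Date` vector.
#' @param calendar A calendar from [make_calendar()].
#' @return Integer row indices into `calendar` (`NA` for dates outside every
#'   week, e.g. the first days of January before the year's first Monday).
#' @export
week_of_date <- function(date, calendar) {
  date <- as.Date(date)
  vapply(date, function(d) {
    i <- which(calendar$monday <= d & d <= calendar$monday + 6)
    if (length(i) == 0L) NA_integer_ else i[1L]
  }, integer(1))
}
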