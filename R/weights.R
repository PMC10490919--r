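#' Day-of-week effort weights
#'
#' The share of a week's fishing effort taken by each day of the week,
#' used both to allocate within-week effort and to effort-weight daily
#' weather when aggregating to the weekly scale. The defaults place 70% of
#' the mass on the weekend (Friday--Sunday), matching the creel program's
#' reported 70/30 weekend/weekday split, with the weekday remainder spread
#' evenly over Monday--Thursday.
#'
#' @param mon,tue,wed,thu,fri,sat,sun Non-negative fractions summing to 1.
#' @return A named numeric vector of length 7 (Monday first) with class
#'   `"effort_weights"`.
#' @examples
#' w <- effort_weights()
#' weekend_share(w) # 0.70
#' @export
effort_weights <- function(mon = 0.075, tue = 0.075, wed = 0.075, thu = 0.075,
                           fri = 0.15, sat = 0.30, sun = 0.25) {
  w <- c(mon = mon, tue = tue, wed = wed, thu = thu,
         fri = fri, sat = sat, sun = sun)
  if (any(w < 0)) stop("effort weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("effort weights must sum to 1")
  class(w) <- "effort_weights"
  w
}

#' Weekend share of the effort weights
#'
#' @param weights An [effort_weights()] vector.
#' @return The total weight on Friday, Saturday, and Sunday.
#' @export
weekend_share <- function(weights) {
  sum(unclass(weights)[c("fri", "sat", "sun")])
}

#' Split weekly effort into daily effort
#'
#' Deterministic allocation of a weekly effort total across Monday--Sunday in
#' proportion to the day-of-week weights, so the weekend share of daily
#' effort equals the weight mass on Friday--Sunday exactly.
#'
#' @param effort Numeric vector of weekly effort totals.
#' @param weights An [effort_weights()] vector.
#' @return A matrix with one row per week and 7 columns (Monday--Sunday).
#' @export
split_weekly_effort <- function(effort, weights = effort_weights()) {
  out <- outer(effort, unclass(weights))
  colnames(out) <- names(unclass(weights))
  out
}
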