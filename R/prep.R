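#' Collapse hourly regional weather to daily summaries
#'
#' Daily summaries follow the conventions of the analysis: daily maximum
#' temperature, daily total precipitation, daily maximum wind speed.
#'
#' @param hourly Data frame with columns `datetime` (POSIXct or anything
#'   `as.POSIXct` accepts, UTC assumed), `region`, `temp`, `precip`, `wind`.
#' @return Data frame `date`, `region`, `tmax`, `precip_total`, `wind_max`.
#' @export
daily_from_hourly <- function(hourly) {
  dt <- as.POSIXct(hourly$datetime, tz = "UTC")
  day <- as.Date(dt, tz = "UTC")
  key <- interaction(hourly$region, day, drop = TRUE)
  hours <- tapply(dt, key, length)
  if (any(hours != 24)) {
    bad <- names(hours)[hours != 24][1]
    stop("partial day in hourly data: ", bad)
  }
  out <- data.frame(
    date = as.Date(tapply(as.character(day), key, `[`, 1)),
    region = tapply(as.character(hourly$region), key, `[`, 1),
    tmax = as.numeric(tapply(hourly$temp, key, max)),
    precip_total = as.numeric(tapply(hourly$precip, key, sum)),
    wind_max = as.numeric(tapply(hourly$wind, key, max))
  )
  rownames(out) <- NULL
  out[order(out$region, out$date), ]
}

#' Default coastal-study-area to region mapping
#'
#' Three eastern basins aggregate to the east region and two western basins
#' to the west; offshore effort cannot be attributed to either region and is
#' dropped.
#'
#' @return Named character vector; `NA` marks areas to drop.
#' @export
area_region_map <- function() {
  c(Pontchartrain = "east", Barataria = "east",
    "Terrebonne_Timbalier" = "east",
    "Vermilion_Teche" = "west", Calcasieu = "west",
    Offshore = NA_character_)
}

#' Aggregate coastal-study-area effort to regions
#'
#' Sums weekly effort over the constituent areas of each region. Areas mapped
#' to `NA` (offshore) are dropped, as are charter rows if a `mode` column is
#' present (only private effort is analyzed).
#'
#' @param effort_area Data frame `year`, `week`, `area`, `effort` (optionally
#'   `mode`).
#' @param map Named character vector mapping area to region, as from
#'   [area_region_map()].
#' @return Data frame `year`, `week`, `region`, `effort`.
#' @export
aggregate_regions <- function(effort_area, map = area_region_map()) {
  unknown <- setdiff(unique(effort_area$area), names(map))
  if (length(unknown)) {
    stop("unmapped coastal study area: ", paste(unknown, collapse = ", "))
  }
  if ("mode" %in% names(effort_area)) {
    effort_area <- effort_area[effort_area$mode == "private", ]
  }
  effort_area$region <- map[effort_area$area]
  effort_area <- effort_area[!is.na(effort_area$region), ]
  if (nrow(effort_area) == 0) {
    return(data.frame(year = numeric(0), week = numeric(0),
                      region = character(0), effort = numeric(0)))
  }
  agg <- stats::aggregate(effort ~ year + week + region, data = effort_area,
                          FUN = sum)
  agg[order(agg$region, agg$year, agg$week), c("year", "week", "region", "effort")]
}

#' Effort-weighted weekly summary of daily values
#'
#' The weekly value of a daily covariate is a weighted average over
#' Monday--Sunday with weights equal to the historical day-of-week shares of
#' fishing effort, so that (say) an uncomfortably cold Saturday depresses the
#' weekly temperature far more than a cold Tuesday.
#'
#' @param daily_values Numeric vector of exactly 7 values ordered
#'   Monday--Sunday (no missing values).
#' @param weights An [effort_weights()] vector.
#' @return The weighted weekly value.
#' @examples
#' uniform <- do.call(effort_weights, as.list(rep(1 / 7, 7)))
#' effort_weighted_week(1:7, uniform) # plain mean: 4
#' @export
effort_weighted_week <- function(daily_values, weights = effort_weights()) {
  if (length(daily_values) != 7 || anyNA(daily_values)) {
    stop("`daily_values` must be 7 non-missing values ordered Monday-Sunday")
  }
  sum(unclass(weights) * daily_values)
}

#' Effort-weighted weekly weather table
#'
#' Applies [effort_weighted_week()] to daily maximum temperature, daily
#' precipitation totals, and daily maximum wind for every survey week and
#' region.
#'
#' @param daily Daily weather table (`date`, `region`, `tmax`,
#'   `precip_total`, `wind_max`).
#' @param calendar Survey calendar from [make_calendar()].
#' @param weights An [effort_weights()] vector.
#' @return Data frame `year`, `week`, `region`, `ew_tmax`, `ew_precip`,
#'   `ew_windmax`.
#' @export
weekly_weather <- function(daily, calendar, weights = effort_weights()) {
  regions <- unique(daily$region)
  out <- lapply(regions, function(rg) {
    d <- daily[daily$region == rg, ]
    d <- d[order(d$date), ]
    pos <- match(calendar$monday, d$date)
    res <- lapply(seq_len(nrow(calendar)), function(i) {
      if (is.na(pos[i]) || pos[i] + 6 > nrow(d) ||
          d$date[pos[i] + 6] != calendar$monday[i] + 6) {
        stop("daily weather for region ", rg, " is missing days in week ",
             calendar$year[i], "-", calendar$week[i])
      }
      rows <- pos[i]:(pos[i] + 6)
      c(ew_tmax = effort_weighted_week(d$tmax[rows], weights),
        ew_precip = effort_weighted_week(d$precip_total[rows], weights),
        ew_windmax = effort_weighted_week(d$wind_max[rows], weights))
    })
    res <- do.call(rbind, res)
    data.frame(year = calendar$year, week = calendar$week, region = rg, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Realign storm warning weeks to landfall weeks
#'
#' Warnings are issued with about 36 hours of lead time, so a warning can be
#' recorded in the survey week before its storm's landfall week. This moves
#' such tropical-storm/hurricane warning counts forward one week to the
#' landfall week; warnings already in the landfall week are untouched, and a
#' warning with no storm landfall in its own or the following week is left in
#' place with a message.
#'
#' @param advisories Data frame `year`, `week`, `region`, `sca_count`,
#'   `ts_warn_count`, `hu_warn_count`.
#' @param storms Storm catalog.
#' @param calendar Survey calendar.
#' @return The advisories table with adjusted warning counts.
#' @export
realign_warning_weeks <- function(advisories, storms, calendar) {
  adv <- advisories
  landfall_idx <- week_of_date(storms$landfall_date, calendar)
  adv_idx <- mapply(function(y, w) {
    which(calendar$year == y & calendar$week == w)[1]
  }, adv$year, adv$week)
  warn_rows <- which(adv$ts_warn_count > 0 | adv$hu_warn_count > 0)
  for (r in warn_rows) {
    same <- which(storms$impacted_region == adv$region[r] &
                    landfall_idx == adv_idx[r])
    if (length(same)) next
    nxt <- which(storms$impacted_region == adv$region[r] &
                   landfall_idx == adv_idx[r] + 1L)
    if (length(nxt)) {
      dest <- which(adv_idx == adv_idx[r] + 1L & adv$region == adv$region[r])
      if (length(dest)) {
        adv$ts_warn_count[dest] <- adv$ts_warn_count[dest] + adv$ts_warn_count[r]
        adv$hu_warn_count[dest] <- adv$hu_warn_count[dest] + adv$hu_warn_count[r]
      } else {
        i <- adv_idx[r] + 1L
        adv <- rbind(adv, data.frame(
          year = calendar$year[i], week = calendar$week[i],
          region = adv$region[r], sca_count = 0L,
          ts_warn_count = adv$ts_warn_count[r],
          hu_warn_count = adv$hu_warn_count[r]))
      }
      adv$ts_warn_count[r] <- 0L
      adv$hu_warn_count[r] <- 0L
    } else {
      message("warning in ", adv$year[r], "-", adv$week[r], " (", adv$region[r],
              ") has no storm landfall within +1 week; left in place")
    }
  }
  adv[order(adv$region, adv$year, adv$week), ]
}

#' Assemble weekly records for one or more regions
#'
#' Joins regional weekly effort, effort-weighted weekly weather, and weekly
#' advisory/warning counts on the survey calendar and attaches the calendar
#' and exclusion flags. If a storm catalog is supplied, warning weeks are
#' realigned to landfall weeks first, and the `warning_week` flag marks weeks
#' with warnings under either the issued or the realigned placement (both
#' weeks see depressed effort when they differ).
#'
#' @param effort Data frame `year`, `week`, `region`, `effort`.
#' @param weather Weekly weather from [weekly_weather()].
#' @param advisories Weekly advisory counts (`sca_count` and optionally
#'   `ts_warn_count`, `hu_warn_count`).
#' @param calendar Survey calendar.
#' @param storms Optional storm catalog for warning realignment.
#' @return A data frame of weekly records, one row per (region, year, week),
#'   with effort, covariates, counts, `month`, and the flags `holiday_week`,
#'   `warning_week`, `pandemic_year`.
#' @export
build_weekly_records <- function(effort, weather, advisories, calendar,
                                 storms = NULL) {
  adv <- advisories
  if (!"ts_warn_count" %in% names(adv)) adv$ts_warn_count <- 0L
  if (!"hu_warn_count" %in% names(adv)) adv$hu_warn_count <- 0L
  raw_warn <- adv
  if (!is.null(storms)) {
    adv <- realign_warning_weeks(adv, storms, calendar)
  }
  key <- function(d) paste(d$region, d$year, d$week, sep = "/")
  rec <- merge(effort, weather, by = c("year", "week", "region"))
  rec <- merge(rec, adv, by = c("year", "week", "region"), all.x = TRUE)
  cnt <- c("sca_count", "ts_warn_count", "hu_warn_count")
  for (cc in cnt) rec[[cc]][is.na(rec[[cc]])] <- 0L
  if (anyDuplicated(key(rec))) stop("duplicate (region, year, week) rows")
  cal_i <- match(paste(rec$year, rec$week), paste(calendar$year, calendar$week))
  if (anyNA(cal_i)) stop("effort weeks outside the survey calendar")
  rec$month <- calendar$month[cal_i]
  rec$monday <- calendar$monday[cal_i]
  rec$holiday_week <- calendar$holiday_week[cal_i]
  issued <- raw_warn[raw_warn$ts_warn_count > 0 | raw_warn$hu_warn_count > 0, ]
  rec$warning_week <- rec$ts_warn_count > 0 | rec$hu_warn_count > 0 |
    key(rec) %in% key(issued)
  rec$pandemic_year <- rec$year == 2020
  rec <- rec[order(rec$region, rec$year, rec$week), ]
  rownames(rec) <- NULL
  rec
}

#' Exclusion filter for the weather analysis
#'
#' Removes, in this order of precedence for the audit reason: weeks with a
#' tropical-storm or hurricane warning, weeks whose Monday--Sunday span
#' contains Memorial Day, Independence Day, or Labor Day, and every week of
#' 2020 (the pandemic year, analyzed separately).
#'
#' @param records Weekly records from [build_weekly_records()].
#' @return The retained records, with the removal audit log (a data frame of
#'   `region`, `year`, `week`, `reason`) attached as attribute `"audit"`.
#' @export
exclusion_filter <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  reason[records$pandemic_year] <- "pandemic_year"
  reason[records$holiday_week] <- "holiday_week"
  reason[records$warning_week] <- "storm_warning"
  drop <- !is.na(reason)
  audit <- data.frame(region = records$region[drop],
                      year = records$year[drop],
                      week = records$week[drop],
                      reason = reason[drop])
  out <- records[!drop, ]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Standardize the design table for the weather model
#'
#' Log-transforms effort (natural log) and standardizes the four predictors
#' -- effort-weighted precipitation, temperature, and wind, and the raw
#' small-craft-advisory count -- by centering on the mean and dividing by one
#' sample (n-1) standard deviation, computed over the retained rows of a
#' single region. Centering and scaling constants are stored for
#' back-transformation.
#'
#' @param records Filtered weekly records for one region.
#' @return A data frame (`log_effort`, `z_precip`, `z_temp`, `z_wind`,
#'   `z_sca`, `month`) of class `"design_table"` with attributes `"center"`,
#'   `"scale"`, and `"region"`.
#' @export
standardize <- function(records) {
  if (length(unique(records$region)) != 1) {
    stop("standardize one region at a time")
  }
  if (any(records$effort <= 0)) stop("effort must be positive to log-transform")
  cols <- c(ew_precip = "z_precip", ew_tmax = "z_temp",
            ew_windmax = "z_wind", sca_count = "z_sca")
  ctr <- numeric(0); scl <- numeric(0)
  out <- data.frame(log_effort = log(records$effort))
  for (src in names(cols)) {
    x <- records[[src]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("predictor has zero variance: ", src)
    }
    out[[cols[[src]]]] <- (x - mean(x)) / s
    ctr[cols[[src]]] <- mean(x)
    scl[cols[[src]]] <- s
  }
  out$month <- records$month
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "region") <- records$region[1]
  class(out) <- c("design_table", "data.frame")
  out
}

#' Pairwise Pearson collinearity screen of the four predictors
#'
#' @param records Weekly records (any number of rows >= 3).
#' @return A list: `matrix` (symmetric 4x4 Pearson correlation matrix with
#'   unit diagonal), `max_abs` (largest absolute off-diagonal correlation),
#'   and `pair` (the predictor pair attaining it).
#' @export
correlation_screen <- function(records) {
  X <- records[, c("ew_precip", "ew_tmax", "ew_windmax", "sca_count")]
  if (nrow(X) < 3) stop("need at least 3 rows for a correlation screen")
  m <- stats::cor(X)
  off <- abs(m); diag(off) <- 0
  i <- which(off == max(off), arr.ind = TRUE)[1, ]
  list(matrix = m, max_abs = max(off),
       pair = c(rownames(m)[i[1]], colnames(m)[i[2]]))
}

#' Within-month sample standard deviation of a weekly covariate
#'
#' @param records Weekly records.
#' @param column Column name (e.g. `"ew_tmax"`).
#' @param month Integer month label 1--12.
#' @return The sample SD over the selected rows.
#' @export
monthly_sd <- function(records, column, month) {
  x <- records[[column]][records$month == month]
  if (length(x) < 3) stop("fewer than 3 rows in month ", month)
  stats::sd(x)
}

#' Conditional squared correlation between two covariates
#'
#' Squared Pearson correlation between two columns within a subset defined by
#' thresholding a third column (e.g. the temperature--wind relationship among
#' weeks at or above 25 degC).
#'
#' @param records Weekly records.
#' @param x,y Column names to correlate.
#' @param by Column used to define the subset.
#' @param threshold Threshold on `by`.
#' @param above If `TRUE`, keep rows with `by >= threshold`, else
#'   `by < threshold`.
#' @return Squared Pearson correlation within the subset.
#' @export
conditional_r2 <- function(records, x, y, by, threshold, above = TRUE) {
  keep <- if (above) records[[by]] >= threshold else records[[by]] < threshold
  if (sum(keep) < 3) stop("subset has fewer than 3 rows")
  stats::cor(records[[x]][keep], records[[y]][keep])^2
}
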