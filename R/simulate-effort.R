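#' Simulate weekly regional fishing effort from the generative model
#'
#' Log effort for a region-week is the monthly intercept plus the monthly
#' standardized-coefficient contributions of the four covariates plus
#' Gaussian noise. Covariates are standardized within region over the full
#' series using the generator's own means and SDs, so the truth-bundle
#' coefficients live on the same standardized scale the fitted model uses.
#'
#' Disturbances are layered on top: in a storm's impacted region, the five
#' weeks starting at the storm's impact week receive an additive log-scale
#' dip of `-storm_dip * (1 + category)` that recovers linearly at
#' `storm_recovery_per_cat * (1 + category)` per week (never overshooting
#' zero), and every 2020 week is multiplied by the pandemic multiplier of its
#' month.
#'
#' @param calendar Survey calendar from [make_calendar()].
#' @param weather Weekly effort-weighted weather from [weekly_weather()].
#' @param advisories Weekly advisory counts from [derive_advisory_counts()]
#'   (warning counts optional).
#' @param storms Storm catalog, or `NULL` for no storm effects.
#' @param truth A [truth_bundle()].
#' @param seed Integer seed for the residual noise.
#' @param pandemic Apply the 2020 multipliers?
#' @return Data frame `year`, `week`, `region`, `effort` (positive).
#' @export
simulate_effort <- function(calendar, weather, advisories, storms = NULL,
                            truth = truth_bundle(), seed = 1,
                            pandemic = TRUE) {
  stopifnot(inherits(truth, "truth_bundle"))
  set.seed(seed)
  regions <- unique(weather$region)
  out <- lapply(regions, function(rg) {
    w <- weather[weather$region == rg, ]
    a <- advisories[advisories$region == rg, ]
    ord <- match(paste(calendar$year, calendar$week),
                 paste(w$year, w$week))
    if (anyNA(ord)) stop("weekly weather is not aligned with the calendar")
    w <- w[ord, ]
    ord_a <- match(paste(calendar$year, calendar$week),
                   paste(a$year, a$week))
    if (anyNA(ord_a)) stop("advisory counts are not aligned with the calendar")
    a <- a[ord_a, ]
    z <- cbind(scale(w$ew_precip), scale(w$ew_tmax),
               scale(w$ew_windmax), scale(a$sca_count))
    m <- calendar$month
    log_eff <- truth$alpha[m] + rowSums(z * truth$beta[m, , drop = FALSE]) +
      stats::rnorm(nrow(calendar), 0, truth$sigma_resid)
    if (!is.null(storms)) {
      st <- storms[storms$impacted_region == rg, ]
      if (nrow(st)) {
        iw <- storm_impact_week(st$landfall_date, calendar)
        for (k in seq_len(nrow(st))) {
          sev <- 1 + st$category[k]
          for (rel in 1:5) {
            i <- iw[k] + rel - 1L
            if (is.na(i) || i > nrow(calendar)) next
            eff <- -truth$storm_dip * sev +
              truth$storm_recovery_per_cat * sev * (rel - 1)
            log_eff[i] <- log_eff[i] + min(eff, 0)
          }
        }
      }
    }
    if (pandemic) {
      in2020 <- calendar$year == 2020
      log_eff[in2020] <- log_eff[in2020] +
        log(truth$pandemic_mult[m[in2020]])
    }
    data.frame(year = calendar$year, week = calendar$week, region = rg,
               effort = exp(log_eff))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Split regional weekly effort into coastal study areas
#'
#' Divides each region's weekly effort among its constituent coastal study
#' areas with fixed shares, and appends a small offshore component
#' (proportional to statewide effort) that downstream aggregation must drop.
#' Shares are deterministic so area-level totals aggregate back to the
#' regional series exactly.
#'
#' @param effort Regional weekly effort table.
#' @param shares Named list of per-region named share vectors (each summing
#'   to 1).
#' @param offshore_frac Offshore effort as a fraction of statewide weekly
#'   effort.
#' @return Data frame `year`, `week`, `area`, `effort`.
#' @export
split_effort_areas <- function(effort,
                               shares = list(
                                 east = c(Pontchartrain = 0.40,
                                          Barataria = 0.35,
                                          "Terrebonne_Timbalier" = 0.25),
                                 west = c("Vermilion_Teche" = 0.55,
                                          Calcasieu = 0.45)),
                               offshore_frac = 0.08) {
  present <- intersect(names(shares), unique(effort$region))
  out <- lapply(present, function(rg) {
    e <- effort[effort$region == rg, ]
    s <- shares[[rg]]
    do.call(rbind, lapply(names(s), function(ar) {
      data.frame(year = e$year, week = e$week, area = ar,
                 effort = e$effort * s[[ar]])
    }))
  })
  out <- do.call(rbind, out)
  tot <- stats::aggregate(effort ~ year + week, data = effort, FUN = sum)
  off <- data.frame(year = tot$year, week = tot$week, area = "Offshore",
                    effort = tot$effort * offshore_frac)
  out <- rbind(out, off)
  rownames(out) <- NULL
  out[order(out$year, out$week, out$area), ]
}

#' Simulate a complete synthetic creel survey
#'
#' End-to-end generator: builds the calendar, simulates daily weather for
#' both regions, derives advisory counts, draws (or accepts) a storm
#' catalog, simulates weekly regional effort with storm and pandemic
#' effects, and splits effort into coastal study areas. All randomness flows
#' from the single `seed` (sub-seeds are derived deterministically from it).
#'
#' @param start_year,end_year Study years.
#' @param seed Master integer seed.
#' @param truth A [truth_bundle()].
#' @param wparams A [weather_process_params()] object.
#' @param weights An [effort_weights()] vector.
#' @param regions Regions to simulate.
#' @param storms A storm catalog, `NULL` to draw the default catalog from the
#'   seed, or `NA` to simulate without storms.
#' @param pandemic Apply 2020 multipliers?
#' @param zones_per_region Forecast zones per region (drives advisory and
#'   warning count magnitudes).
#' @return A list of class `"creel_simulation"` with elements `calendar`,
#'   `daily_weather`, `weekly_weather`, `advisories`, `storms`,
#'   `effort`, `effort_area`, `weights`, `truth`, `seed`.
#' @export
simulate_survey <- function(start_year = 2015, end_year = 2021, seed = 1,
                            truth = truth_bundle(),
                            wparams = weather_process_params(),
                            weights = effort_weights(),
                            regions = c("east", "west"),
                            storms = NULL, pandemic = TRUE,
                            zones_per_region = c(east = 7, west = 4)) {
  calendar <- make_calendar(start_year, end_year)
  daily <- simulate_daily_weather(wparams, regions, start_year, end_year,
                                  seed = seed)
  wk <- weekly_weather(daily, calendar, weights)
  adv <- derive_advisory_counts(daily, calendar,
                                zones_per_region = zones_per_region)
  if (is.null(storms)) {
    yrs <- seq.int(start_year, end_year)
    # short records cannot hold 12 storms at the full between-storm spacing
    storms <- sample_storm_catalog(seed = seed + 1L, years = yrs,
                                   min_gap_days = if (length(yrs) >= 3) 42 else 7)
  } else if (length(storms) == 1L && is.na(storms)) {
    storms <- NULL
  }
  if (!is.null(storms)) {
    warn <- storm_warning_counts(storms, calendar,
                                 zones_per_region = zones_per_region)
    adv <- merge(adv, warn, by = c("year", "week", "region"), all.x = TRUE)
    adv$ts_warn_count[is.na(adv$ts_warn_count)] <- 0L
    adv$hu_warn_count[is.na(adv$hu_warn_count)] <- 0L
  } else {
    adv$ts_warn_count <- 0L
    adv$hu_warn_count <- 0L
  }
  adv <- adv[order(adv$region, adv$year, adv$week), ]
  eff <- simulate_effort(calendar, wk, adv, storms, truth,
                         seed = seed + 2L, pandemic = pandemic)
  out <- list(calendar = calendar, daily_weather = daily,
              weekly_weather = wk, advisories = adv, storms = storms,
              effort = eff, effort_area = split_effort_areas(eff),
              weights = weights, truth = truth, seed = seed)
  class(out) <- "creel_simulation"
  out
}

#' Write the synthetic survey tables to CSV
#'
#' Writes the four analysis input schemas (area-level weekly effort, daily
#' regional weather, weekly advisory counts, storm catalog) plus the truth
#' parameters as YAML for parameter-recovery checks.
#'
#' @param sim A [simulate_survey()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(sim, dir) {
  stopifnot(inherits(sim, "creel_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$effort_area, file.path(dir, "effort_by_area.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$daily_weather, file.path(dir, "daily_weather.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$advisories, file.path(dir, "advisories.csv"),
                   row.names = FALSE)
  if (!is.null(sim$storms)) {
    utils::write.csv(sim$storms, file.path(dir, "storms.csv"),
                     row.names = FALSE)
  }
  write_truth(sim$truth, file.path(dir, "truth.yml"))
  invisible(dir)
}
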