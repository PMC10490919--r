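#' Parameters of the synthetic daily weather process
#'
#' The generator emulates regional daily weather summaries for a subtropical
#' coast: daily maximum temperature follows a sinusoidal annual cycle plus
#' AR(1) noise whose stationary standard deviation is larger in winter than
#' in summer (so weekly effort-weighted temperature is several times more
#' variable in January than in June); precipitation is zero-inflated gamma
#' with a wetter warm season; daily maximum wind is Weibull with a windier
#' cool season. Region offsets make the west slightly warmer and less windy
#' than the east.
#'
#' Defaults are calibrated so that, with the default day-of-week weights, the
#' weekly effort-weighted temperature SD is about 3.3 degC in January and
#' about 1.5 degC in midsummer, and cool-season wind exceeds the small-craft
#' threshold often enough to produce advisory totals in the thousands over a
#' 7-year record in a multi-zone region.
#'
#' @param temp_mean_annual Annual-mean daily maximum temperature (degC).
#' @param temp_amplitude Half-range of the annual temperature cycle (degC).
#' @param temp_peak_doy Day of year at which the cycle peaks.
#' @param temp_ar1 AR(1) coefficient of daily temperature noise (|ar1| < 1).
#' @param temp_noise_sd_winter,temp_noise_sd_summer Stationary SD of the
#'   temperature noise in midwinter and midsummer (degC); interpolated
#'   sinusoidally in between.
#' @param precip_wet_prob_winter,precip_wet_prob_summer Probability a day is
#'   wet, by season.
#' @param precip_gamma_shape,precip_gamma_scale Gamma parameters of wet-day
#'   precipitation totals (mm).
#' @param wind_weibull_shape Weibull shape of daily maximum wind.
#' @param wind_scale_winter,wind_scale_summer Weibull scale (m/s) in
#'   midwinter and midsummer.
#' @param region_temp_offset,region_wind_mult Named numeric vectors of
#'   additive temperature offsets (degC) and multiplicative wind factors per
#'   region.
#' @return A list with class `"weather_process_params"`.
#' @export
weather_process_params <- function(temp_mean_annual = 24,
                                   temp_amplitude = 9,
                                   temp_peak_doy = 199,
                                   temp_ar1 = 0.7,
                                   temp_noise_sd_winter = 4.4,
                                   temp_noise_sd_summer = 2.0,
                                   precip_wet_prob_winter = 0.30,
                                   precip_wet_prob_summer = 0.45,
                                   precip_gamma_shape = 0.8,
                                   precip_gamma_scale = 14,
                                   wind_weibull_shape = 2,
                                   wind_scale_winter = 10.5,
                                   wind_scale_summer = 7.5,
                                   region_temp_offset = c(east = 0, west = 0.5),
                                   region_wind_mult = c(east = 1, west = 0.9)) {
  p <- list(temp_mean_annual = temp_mean_annual,
            temp_amplitude = temp_amplitude,
            temp_peak_doy = temp_peak_doy,
            temp_ar1 = temp_ar1,
            temp_noise_sd_winter = temp_noise_sd_winter,
            temp_noise_sd_summer = temp_noise_sd_summer,
            precip_wet_prob_winter = precip_wet_prob_winter,
            precip_wet_prob_summer = precip_wet_prob_summer,
            precip_gamma_shape = precip_gamma_shape,
            precip_gamma_scale = precip_gamma_scale,
            wind_weibull_shape = wind_weibull_shape,
            wind_scale_winter = wind_scale_winter,
            wind_scale_summer = wind_scale_summer,
            region_temp_offset = region_temp_offset,
            region_wind_mult = region_wind_mult)
  probs <- c(p$precip_wet_prob_winter, p$precip_wet_prob_summer)
  if (any(probs < 0 | probs > 1)) stop("wet-day probabilities must lie in [0, 1]")
  if (abs(p$temp_ar1) >= 1) stop("|temp_ar1| must be < 1")
  pos <- c(p$precip_gamma_shape, p$precip_gamma_scale, p$wind_weibull_shape,
           p$wind_scale_winter, p$wind_scale_summer)
  if (any(pos <= 0)) stop("shape and scale parameters must be positive")
  if (any(p$temp_noise_sd_winter < 0, p$temp_noise_sd_summer < 0)) {
    stop("noise SDs must be non-negative")
  }
  class(p) <- "weather_process_params"
  p
}

# Seasonal mixing weight: 1 at the summer peak day, 0 in midwinter.
season_weight <- function(doy, peak_doy) {
  (1 + cos(2 * pi * (doy - peak_doy) / 365.25)) / 2
}

season_interp <- function(doy, winter_val, summer_val, peak_doy) {
  winter_val + (summer_val - winter_val) * season_weight(doy, peak_doy)
}

#' Simulate daily regional weather summaries
#'
#' Generates one row per day per region: daily maximum temperature (degC),
#' daily total precipitation (mm), and daily maximum wind speed (m/s). The
#' simulated span runs from January 1 of the first year through January 7 of
#' the year after the last, so that the final Monday-start survey week of the
#' last year (which can spill a few days into the next January) is fully
#' covered.
#'
#' @param params A [weather_process_params()] object.
#' @param regions Character vector of region identifiers; must have matching
#'   entries in the params' region offset vectors.
#' @param start_year,end_year Years to cover (inclusive).
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @return A data frame with columns `date`, `region`, `tmax`,
#'   `precip_total`, `wind_max`.
#' @export
simulate_daily_weather <- function(params = weather_process_params(),
                                   regions = c("east", "west"),
                                   start_year = 2015, end_year = 2021,
                                   seed = 1) {
  stopifnot(inherits(params, "weather_process_params"))
  missing_r <- setdiff(regions, names(params$region_temp_offset))
  if (length(missing_r)) {
    stop("no region offsets for: ", paste(missing_r, collapse = ", "))
  }
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-01-07", end_year + 1)), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  n <- length(dates)
  out <- lapply(regions, function(rg) {
    mu <- params$temp_mean_annual + params$region_temp_offset[[rg]] +
      params$temp_amplitude * cos(2 * pi * (doy - params$temp_peak_doy) / 365.25)
    s <- season_interp(doy, params$temp_noise_sd_winter,
                       params$temp_noise_sd_summer, params$temp_peak_doy)
    phi <- params$temp_ar1
    eps <- numeric(n)
    eps[1] <- stats::rnorm(1, 0, s[1])
    innov_sd <- s * sqrt(1 - phi^2)
    z <- stats::rnorm(n)
    for (i in seq_len(n)[-1]) {
      eps[i] <- phi * eps[i - 1] + innov_sd[i] * z[i]
    }
    tmax <- mu + eps

    wet_p <- season_interp(doy, params$precip_wet_prob_winter,
                           params$precip_wet_prob_summer, params$temp_peak_doy)
    wet <- stats::runif(n) < wet_p
    precip <- ifelse(wet,
                     stats::rgamma(n, shape = params$precip_gamma_shape,
                                   scale = params$precip_gamma_scale),
                     0)

    wscale <- season_interp(doy, params$wind_scale_winter,
                            params$wind_scale_summer, params$temp_peak_doy) *
      params$region_wind_mult[[rg]]
    wind <- stats::rweibull(n, shape = params$wind_weibull_shape,
                            scale = wscale)

    data.frame(date = dates, region = rg, tmax = tmax,
               precip_total = precip, wind_max = wind)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Derive weekly small-craft-advisory counts from daily wind
#'
#' A small craft advisory is issued for a forecast zone on any day whose
#' maximum wind reaches the advisory threshold (21 kt is about 10.8 m/s), so
#' the weekly regional count is the number of exceedance days in the week
#' multiplied by the number of marine forecast zones in the region. Counts
#' from persistent rough-sea weeks over many zones therefore reach the tens.
#'
#' @param daily Daily weather table from [simulate_daily_weather()] (or the
#'   same schema from real data).
#' @param calendar Survey calendar from [make_calendar()].
#' @param wind_threshold Advisory wind threshold in m/s (must be positive).
#' @param zones_per_region Named integer vector: number of forecast zones per
#'   region, or a single number applied to every region.
#' @return Data frame `year`, `week`, `region`, `sca_count`.
#' @export
derive_advisory_counts <- function(daily, calendar, wind_threshold = 10.8,
                                   zones_per_region = c(east = 7, west = 4)) {
  if (wind_threshold <= 0) stop("`wind_threshold` must be positive")
  regions <- unique(daily$region)
  if (length(zones_per_region) == 1L && is.null(names(zones_per_region))) {
    zones_per_region <- stats::setNames(rep(zones_per_region, length(regions)),
                                        regions)
  }
  out <- lapply(regions, function(rg) {
    d <- daily[daily$region == rg, ]
    idx <- week_of_date(d$date, calendar)
    keep <- !is.na(idx)
    d <- d[keep, ]; idx <- idx[keep]
    if (any(tabulate(idx, nbins = nrow(calendar)) %in% 1:6)) {
      stop("daily table must cover whole survey weeks for region ", rg)
    }
    exceed <- tapply(d$wind_max >= wind_threshold, idx, sum)
    rows <- as.integer(names(exceed))
    data.frame(year = calendar$year[rows], week = calendar$week[rows],
               region = rg,
               sca_count = as.integer(exceed) * zones_per_region[[rg]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$region, out$year, out$week), ]
}
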