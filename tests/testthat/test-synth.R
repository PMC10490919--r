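test_that("effort weights validate and default to a 70% weekend share", {
  w <- effort_weights()
  expect_equal(sum(unclass(w)), 1)
  expect_equal(weekend_share(w), 0.70)
  expect_error(effort_weights(mon = -0.1, sat = 0.475), "non-negative")
  expect_error(effort_weights(mon = 0.2), "sum to 1")
})

test_that("daily effort split puts exactly the weekend weight mass on Fri-Sun", {
  set.seed(1)
  eff <- rlnorm(30, 9, 0.5)
  daily <- split_weekly_effort(eff)
  expect_equal(rowSums(daily), eff)
  share <- rowSums(daily[, c("fri", "sat", "sun")]) / rowSums(daily)
  expect_equal(share, rep(0.70, 30))
})

test_that("noise-free weather reduces to the deterministic seasonal cycle", {
  p <- weather_process_params(temp_noise_sd_winter = 0,
                              temp_noise_sd_summer = 0, temp_ar1 = 0,
                              precip_wet_prob_winter = 0,
                              precip_wet_prob_summer = 0)
  d <- simulate_daily_weather(p, "east", 2016, 2016, seed = 1)
  doy <- as.POSIXlt(d$date)$yday + 1
  mu <- p$temp_mean_annual + p$region_temp_offset[["east"]] +
    p$temp_amplitude * cos(2 * pi * (doy - p$temp_peak_doy) / 365.25)
  expect_equal(d$tmax, mu)
  expect_true(all(d$precip_total == 0))
})

test_that("daily weather is reproducible for a fixed seed", {
  a <- simulate_daily_weather(seed = 9, start_year = 2015, end_year = 2015)
  b <- simulate_daily_weather(seed = 9, start_year = 2015, end_year = 2015)
  expect_identical(a, b)
  c <- simulate_daily_weather(seed = 10, start_year = 2015, end_year = 2015)
  expect_false(identical(a$tmax, c$tmax))
})

test_that("weekly effort-weighted January temperature variability matches the winter calibration", {
  # long record so the sample SD of January weekly values is stable
  d <- simulate_daily_weather(regions = "east", start_year = 2000,
                              end_year = 2029, seed = 123)
  cal <- make_calendar(2000, 2029)
  wk <- weekly_weather(d, cal)
  jan_sd <- sd(wk$ew_tmax[cal$month == 1])
  expect_gt(jan_sd, 2.8)
  expect_lt(jan_sd, 3.8)
  jul_sd <- sd(wk$ew_tmax[cal$month == 7])
  expect_lt(jul_sd, jan_sd / 1.5)
})

test_that("advisory counts are exceedance days times forecast zones", {
  cal <- make_calendar(2019, 2019)
  dates <- seq(min(cal$monday), max(cal$monday) + 6, by = "day")
  wind <- rep(5, length(dates))
  # week 10: three days at or above the threshold
  wk10 <- which(dates >= cal$monday[10] & dates <= cal$monday[10] + 6)
  wind[wk10[c(2, 4, 6)]] <- 12
  daily <- data.frame(date = dates, region = "east", tmax = 20,
                      precip_total = 0, wind_max = wind)
  adv <- derive_advisory_counts(daily, cal, wind_threshold = 10.8,
                                zones_per_region = c(east = 4))
  expect_equal(adv$sca_count[adv$week == 10], 12L)
  expect_true(all(adv$sca_count[adv$week != 10] == 0L))
  expect_error(derive_advisory_counts(daily, cal, wind_threshold = -1),
               "positive")
})

test_that("advisory totals over 7 years are of the observed order of magnitude", {
  sim <- sim_full()
  east_total <- sum(sim$advisories$sca_count[sim$advisories$region == "east"])
  expect_gt(east_total, 2000)
  expect_lt(east_total, 8000)
})

test_that("the storm catalog reproduces the fixed severity mix", {
  storms <- sample_storm_catalog(seed = 1)
  expect_equal(nrow(storms), 12)
  expect_equal(sort(storms$category), c(0, 0, 0, 0, 0, 0, 1, 1, 2, 3, 4, 4))
  expect_true(all(diff(as.numeric(storms$landfall_date)) > 0))
  months <- as.POSIXlt(storms$landfall_date)$mon + 1
  expect_true(all(months %in% 6:11))
  expect_true(all(as.POSIXlt(storms$landfall_date)$year + 1900 %in% 2015:2021))
  other <- sample_storm_catalog(seed = 2)
  expect_equal(sort(other$category), sort(storms$category))
  expect_false(identical(other$landfall_date, storms$landfall_date))
})

test_that("effort reduces to exp(monthly intercept) in the deterministic limit", {
  truth <- truth_bundle(beta = matrix(0, 12, 4), sigma_resid = 0)
  sim <- simulate_survey(seed = 3, truth = truth, storms = NA,
                         pandemic = FALSE, regions = "east",
                         zones_per_region = c(east = 7))
  expect_equal(sim$effort$effort,
               exp(truth$alpha[sim$calendar$month]))
})

test_that("2020 effort carries the monthly pandemic multipliers exactly in the noise-free limit", {
  truth <- truth_bundle(beta = matrix(0, 12, 4), sigma_resid = 0)
  sim <- simulate_survey(seed = 3, truth = truth, storms = NA,
                         pandemic = TRUE, regions = "east",
                         zones_per_region = c(east = 7))
  m <- sim$calendar$month
  expected <- exp(truth$alpha[m]) *
    ifelse(sim$calendar$year == 2020, truth$pandemic_mult[m], 1)
  expect_equal(sim$effort$effort, expected)
})

test_that("expected log effort rises over the five weeks after a severe storm", {
  cal <- make_calendar(2018, 2018)
  daily <- simulate_daily_weather(regions = "east", start_year = 2018,
                                  end_year = 2018, seed = 77)
  wk <- weekly_weather(daily, cal)
  adv <- derive_advisory_counts(daily, cal, zones_per_region = c(east = 7))
  storm <- data.frame(storm_id = "S01", name = "Storm-A",
                      landfall_date = as.Date("2018-08-16"), # a Thursday
                      category = 4L, impacted_region = "east")
  truth <- truth_bundle(beta = matrix(0, 12, 4))
  iw <- storm_impact_week(storm$landfall_date, cal)
  mean_log <- rowMeans(vapply(1:200, function(r) {
    eff <- simulate_effort(cal, wk, adv, storm, truth, seed = 1000 + r)
    log(eff$effort[iw + 0:4])
  }, numeric(5)))
  expect_true(all(diff(mean_log) > 0))
})

test_that("the full survey simulation is bit-identical under a fixed seed", {
  a <- simulate_survey(seed = 21, start_year = 2016, end_year = 2017)
  b <- simulate_survey(seed = 21, start_year = 2016, end_year = 2017)
  expect_identical(a$effort, b$effort)
  expect_identical(a$daily_weather, b$daily_weather)
  expect_identical(a$storms, b$storms)
  expect_true(all(a$effort$effort > 0))
})

test_that("truth bundles validate their generative invariants", {
  expect_error(truth_bundle(Sigma = matrix(c(1, 2, 2, 1), 2)), "positive-definite")
  expect_error(truth_bundle(sigma_resid = -1), "non-negative")
  expect_error(truth_bundle(pandemic_mult = rep(0, 12)), "positive")
  tr <- truth_bundle(seed = 1)
  expect_equal(dim(tr$beta), c(12L, 4L))
  # drawn betas differ from the monthly means; means follow the gamma line
  expect_false(all(tr$beta[, 2] == tr$gamma0 + tr$gamma1 * ((1:12) - 6.5)))
})
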