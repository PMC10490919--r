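make_hourly <- function(days, region = "east", temp = 20, precip = 0.5,
                        wind = 0) {
  do.call(rbind, lapply(seq_along(days), function(i) {
    data.frame(datetime = as.POSIXct(days[i], tz = "UTC") + 3600 * (0:23),
               region = region, temp = temp, precip = precip, wind = wind)
  }))
}

test_that("hourly weather collapses to daily max/sum/max summaries", {
  h <- make_hourly(as.Date("2018-06-01"))
  h$wind <- c(3, 9, 5, rep(0, 21))
  d <- daily_from_hourly(h)
  expect_equal(d$tmax, 20)
  expect_equal(d$precip_total, 12.0) # 24 x 0.5 mm
  expect_equal(d$wind_max, 9)
})

test_that("a partial day in the hourly record is an error naming the date", {
  h <- make_hourly(as.Date("2018-06-01"))
  expect_error(daily_from_hourly(h[-1, ]), "2018-06-01")
})

test_that("area effort aggregates to regions, dropping offshore and charter", {
  ea <- data.frame(year = 2016, week = 1,
                   area = c("Pontchartrain", "Barataria",
                            "Terrebonne_Timbalier", "Vermilion_Teche",
                            "Calcasieu", "Offshore"),
                   effort = c(10, 20, 30, 5, 7, 99))
  out <- aggregate_regions(ea)
  expect_equal(out$effort[out$region == "east"], 60)
  expect_equal(out$effort[out$region == "west"], 12)
  expect_false("Offshore" %in% out$region)
  expect_equal(nrow(out), 2)
  ea$mode <- c("private", "charter", "private", "private", "private", "private")
  out2 <- aggregate_regions(ea)
  expect_equal(out2$effort[out2$region == "east"], 40)
  ea$area[1] <- "Atchafalaya"
  expect_error(aggregate_regions(ea), "Atchafalaya")
})

test_that("offshore-only weeks produce no regional rows", {
  ea <- data.frame(year = 2016, week = 2, area = "Offshore", effort = 50)
  expect_equal(nrow(aggregate_regions(ea)), 0)
})

test_that("effort weighting reduces to the mean under uniform weights", {
  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(7, 20, 5)
    expect_equal(effort_weighted_week(v, uniform_weights()), mean(v))
  }
  # point mass on Saturday returns Saturday's value
  sat_only <- effort_weights(0, 0, 0, 0, 0, 1, 0)
  v <- c(1, 2, 3, 4, 5, 42, 7)
  expect_equal(effort_weighted_week(v, sat_only), 42)
  expect_error(effort_weighted_week(1:6), "7 non-missing")
})

test_that("a cold Saturday depresses the weekly value more than a cold Tuesday", {
  w <- effort_weights()
  base <- rep(20, 7)
  cold_sat <- base; cold_sat[6] <- 5
  cold_tue <- base; cold_tue[2] <- 5
  ew_sat <- effort_weighted_week(cold_sat, w)
  ew_tue <- effort_weighted_week(cold_tue, w)
  # hand-computed weighted sums
  expect_equal(ew_sat, 20 - 15 * 0.30)
  expect_equal(ew_tue, 20 - 15 * 0.075)
  expect_lt(ew_sat, ew_tue)
})

test_that("weekly weather errors when days are missing", {
  cal <- make_calendar(2019, 2019)
  d <- simulate_daily_weather(regions = "east", start_year = 2019,
                              end_year = 2019, seed = 1)
  expect_error(weekly_weather(d[-10, ], cal), "missing days")
})

test_that("warnings issued the week before landfall move to the landfall week", {
  cal <- make_calendar(2019, 2019)
  # landfall Monday 2019-08-12 (week w); a 36-h-lead warning falls in week w-1
  storm <- data.frame(storm_id = "S01", name = "A",
                      landfall_date = as.Date("2019-08-12"),
                      category = 1L, impacted_region = "east")
  lf_wk <- cal$week[week_of_date(storm$landfall_date, cal)]
  adv <- data.frame(year = 2019, week = c(lf_wk - 1, lf_wk), region = "east",
                    sca_count = c(2L, 0L), ts_warn_count = c(6L, 0L),
                    hu_warn_count = c(6L, 0L))
  out <- realign_warning_weeks(adv, storm, cal)
  expect_equal(out$ts_warn_count[out$week == lf_wk - 1], 0L)
  expect_equal(out$ts_warn_count[out$week == lf_wk], 6L)
  expect_equal(out$hu_warn_count[out$week == lf_wk], 6L)
  # small-craft counts untouched
  expect_equal(out$sca_count[out$week == lf_wk - 1], 2L)
})

test_that("warnings already in the landfall week, or with no storm, stay put", {
  cal <- make_calendar(2019, 2019)
  storm <- data.frame(storm_id = "S01", name = "A",
                      landfall_date = as.Date("2019-08-15"), # Thursday
                      category = 0L, impacted_region = "east")
  lf_wk <- cal$week[week_of_date(storm$landfall_date, cal)]
  adv <- data.frame(year = 2019, week = lf_wk, region = "east",
                    sca_count = 0L, ts_warn_count = 4L, hu_warn_count = 0L)
  expect_identical(realign_warning_weeks(adv, storm, cal), adv)
  # no storms at all: counts unchanged, a message is logged
  none <- storm[0, ]
  expect_message(out <- realign_warning_weeks(adv, none, cal),
                 "no storm landfall")
  expect_equal(out$ts_warn_count, adv$ts_warn_count)
})

test_that("the exclusion filter removes warning, holiday, and pandemic weeks with an audit trail", {
  sim <- sim_full()
  eff <- aggregate_regions(sim$effort_area)
  rec <- build_weekly_records(eff, sim$weekly_weather, sim$advisories,
                              sim$calendar, sim$storms)
  expect_equal(nrow(rec), 728) # 364 weeks x 2 regions before filtering
  kept <- exclusion_filter(rec)
  audit <- attr(kept, "audit")
  expect_equal(nrow(kept) + nrow(audit), nrow(rec))
  expect_true(all(kept$year != 2020))
  expect_true(all(!kept$holiday_week))
  expect_true(all(kept$ts_warn_count == 0 & kept$hu_warn_count == 0))
  expect_setequal(unique(audit$reason),
                  c("storm_warning", "holiday_week", "pandemic_year"))
  # every 2020 week is gone even without warnings or holidays
  expect_equal(sum(audit$year == 2020), 104)
})

test_that("standardization centers and scales with the sample SD", {
  rec <- data.frame(region = "east", effort = c(10, 20, 30),
                    ew_precip = c(1, 2, 3), ew_tmax = c(5, 10, 15),
                    ew_windmax = c(2, 4, 6), sca_count = c(0, 3, 6),
                    month = 1:3)
  d <- standardize(rec)
  expect_equal(d$z_precip, c(-1, 0, 1))
  expect_equal(d$log_effort, log(c(10, 20, 30)))
  expect_equal(unname(attr(d, "scale")["z_precip"]), 1)
  # idempotence: standardizing already-standardized columns changes nothing
  rec2 <- rec
  rec2$ew_precip <- d$z_precip; rec2$ew_tmax <- d$z_temp
  rec2$ew_windmax <- d$z_wind; rec2$sca_count <- d$z_sca
  d2 <- standardize(rec2)
  expect_equal(d2$z_precip, d$z_precip, tolerance = 1e-9)
  expect_equal(d2$z_sca, d$z_sca, tolerance = 1e-9)
})

test_that("standardization rejects constant predictors and mixed regions", {
  rec <- data.frame(region = "east", effort = c(10, 20, 30),
                    ew_precip = c(1, 1, 1), ew_tmax = c(5, 10, 15),
                    ew_windmax = c(2, 4, 6), sca_count = c(0, 3, 6),
                    month = 1:3)
  expect_error(standardize(rec), "ew_precip")
  rec$ew_precip <- 1:3
  rec$region <- c("east", "east", "west")
  expect_error(standardize(rec), "one region")
})

test_that("the collinearity screen reports the extreme pair", {
  x <- c(1, 2, 3, 4, 5)
  rec <- data.frame(ew_precip = x, ew_tmax = 2 * x,
                    ew_windmax = c(2, 1, 4, 3, 6), sca_count = -x)
  cs <- correlation_screen(rec)
  expect_equal(diag(cs$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cs$matrix, t(cs$matrix))
  expect_equal(cs$matrix["ew_precip", "ew_tmax"], 1)
  expect_equal(cs$matrix["ew_precip", "sca_count"], -1)
  expect_equal(cs$max_abs, 1)
  expect_error(correlation_screen(rec[1:2, ]), "at least 3")
})

test_that("descriptive statistics match hand computations", {
  rec <- data.frame(month = rep(1, 3), ew_tmax = c(7, 7, 7),
                    ew_windmax = c(1, 2, 3))
  expect_equal(monthly_sd(rec, "ew_tmax", 1), 0)
  rec2 <- data.frame(ew_tmax = c(1, 2, 3), ew_windmax = c(2, 1, 3),
                     month = 1)
  expect_equal(conditional_r2(rec2, "ew_tmax", "ew_windmax",
                              by = "ew_tmax", threshold = 0), 0.25)
  lin <- data.frame(ew_tmax = 1:5, ew_windmax = 2 * (1:5) + 1, month = 1)
  expect_equal(conditional_r2(lin, "ew_tmax", "ew_windmax",
                              by = "ew_tmax", threshold = 0), 1)
  expect_error(conditional_r2(rec2, "ew_tmax", "ew_windmax",
                              by = "ew_tmax", threshold = 99), "fewer than 3")
})
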