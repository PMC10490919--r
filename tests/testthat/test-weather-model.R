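test_that("model specs validate their schedule arithmetic", {
  expect_error(weather_model_spec(chains = 1), "at least 2")
  expect_error(weather_model_spec(iterations = 100, burnin = 100), "smaller")
  expect_error(weather_model_spec(thin = 0), "at least 1")
  expect_equal(retained_draws(3, 100000, 30000, 2), 105000)
  expect_equal(retained_draws(weather_model_spec()), 6000)
  expect_equal(retained_draws(3, 4000, 2000, 1), 6000)
})

test_that("dropping the month trend nests the plain exchangeable-mean model", {
  d <- sim_plain()$design
  with_trend <- build_weather_model(d, weather_model_spec())
  without <- build_weather_model(d, weather_model_spec(month_trend = FALSE))
  expect_true(grepl("g1", with_trend$code))
  expect_false(grepl("g1", without$code))
  expect_null(without$data$zm)
  expect_false("g1" %in% without$monitors)
})

test_that("months without data are reported by name", {
  d <- sim_plain()$design
  d11 <- d[d$month != 12, ]
  attr(d11, "region") <- "east"
  expect_error(build_weather_model(d11), "12")
})

test_that("the log joint density is finite at the generative truth", {
  sim <- sim_plain()
  truth <- truth_bundle(seed = 42)
  d <- sim$design
  z <- as.matrix(d[, c("z_precip", "z_temp", "z_wind", "z_sca")])
  m <- d$month
  mu <- truth$alpha[m] + rowSums(z * truth$beta[m, ])
  loglik <- sum(dnorm(d$log_effort, mu, truth$sigma_resid, log = TRUE))
  zm <- (1:12) - 6.5
  mu_month <- cbind(truth$mu["precip"], truth$gamma0 + truth$gamma1 * zm,
                    truth$mu["wind"], truth$mu["sca"])
  Sinv <- solve(truth$Sigma)
  logl2 <- sum(vapply(1:12, function(j) {
    dev <- truth$beta[j, ] - mu_month[j, ]
    -0.5 * (determinant(truth$Sigma)$modulus + t(dev) %*% Sinv %*% dev +
              4 * log(2 * pi))
  }, numeric(1)))
  expect_true(is.finite(loglik + logl2))
})

test_that("the fitted model recovers monthly effects with coherent intervals", {
  sim <- sim_plain()
  truth <- truth_bundle(seed = 42)
  fit <- fit_weather_model(build_weather_model(sim$design), seed = 7)
  expect_equal(fit$retained, 6000)
  expect_lt(fit$rhat$max_rhat, 1.1)
  eff <- summarize_monthly_effects(fit)
  expect_equal(nrow(eff), 48)
  expect_true(all(eff$lower <= eff$mean & eff$mean <= eff$upper))
  expect_equal(eff$credible, eff$lower > 0 | eff$upper < 0)
  # recovery: most true monthly coefficients inside their intervals
  vars <- c("precipitation", "temperature", "wind", "sca")
  hits <- vapply(seq_len(nrow(eff)), function(i) {
    tv <- truth$beta[eff$month[i], match(eff$variable[i], vars)]
    tv >= eff$lower[i] && tv <= eff$upper[i]
  }, logical(1))
  expect_gt(mean(hits), 0.85)
  .fixtures$weather_fit <- fit
})

test_that("posterior summaries are stable under row permutation of the design", {
  sim <- sim_plain()
  fit1 <- .fixtures$weather_fit
  if (is.null(fit1)) fit1 <- fit_weather_model(build_weather_model(sim$design), seed = 7)
  set.seed(99)
  d2 <- sim$design[sample(nrow(sim$design)), ]
  class(d2) <- class(sim$design)
  attr(d2, "region") <- "east"
  fit2 <- suppressWarnings(fit_weather_model(build_weather_model(d2), seed = 7))
  e1 <- summarize_monthly_effects(fit1)
  e2 <- summarize_monthly_effects(fit2)
  expect_lt(max(abs(e1$mean - e2$mean)), 0.02)
  expect_gt(cor(e1$mean, e2$mean), 0.995)
})

test_that("the temperature month trend is recovered across repeated simulations", {
  wp <- weather_process_params()
  daily <- simulate_daily_weather(wp, "east", 2015, 2021, seed = 400)
  cal <- make_calendar(2015, 2021)
  wk <- weekly_weather(daily, cal)
  adv <- derive_advisory_counts(daily, cal, zones_per_region = c(east = 7))
  spec <- weather_model_spec(iterations = 2000, burnin = 1000)
  g1_hat <- vapply(1:20, function(r) {
    tr <- truth_bundle(seed = 300 + r, gamma1 = -0.05)
    eff <- simulate_effort(cal, wk, adv, storms = NULL, truth = tr,
                           seed = 700 + r, pandemic = FALSE)
    rec <- build_weekly_records(eff, wk, adv, cal)
    fit <- suppressWarnings(
      fit_weather_model(build_weather_model(standardize(rec), spec),
                        seed = r))
    tr_sum <- temperature_month_trend(fit)
    tr_sum$summary$mean[tr_sum$summary$parameter == "gamma1"]
  }, numeric(1))
  expect_lt(abs(mean(g1_hat) - (-0.05)), 0.03)
})

test_that("trend summaries expose the fitted line and flag direction", {
  fit <- .fixtures$weather_fit
  if (is.null(fit)) fit <- fit_weather_model(build_weather_model(sim_plain()$design), seed = 7)
  tr <- temperature_month_trend(fit)
  expect_equal(nrow(tr$line), 12)
  g0 <- tr$summary$mean[1]; g1 <- tr$summary$mean[2]
  expect_equal(tr$line$value, g0 + g1 * ((1:12) - 6.5))
  no_trend <- suppressWarnings(fit_weather_model(
    build_weather_model(sim_plain()$design,
                        weather_model_spec(month_trend = FALSE,
                                           iterations = 1000, burnin = 500)),
    seed = 2))
  expect_error(temperature_month_trend(no_trend), "without the month trend")
})

test_that("posterior means match least squares in the degenerate non-hierarchical limit", {
  set.seed(31)
  n <- 500
  z <- matrix(rnorm(n * 4), n, 4)
  y <- 9 + z %*% c(-0.06, 0.1, -0.06, -0.03) + rnorm(n, 0, 0.2)
  d <- data.frame(log_effort = as.numeric(y), z_precip = z[, 1],
                  z_temp = z[, 2], z_wind = z[, 3], z_sca = z[, 4],
                  month = 1L)
  class(d) <- c("design_table", "data.frame")
  spec <- weather_model_spec(n_months = 1, month_trend = FALSE)
  fit <- fit_weather_model(build_weather_model(d, spec), seed = 3)
  ols <- coef(lm(log_effort ~ z_precip + z_temp + z_wind + z_sca, d))
  # joint check at the 2-MCSE scale: sum of squared (diff / MCSE) over the
  # four coefficients against a chi-square bound
  zstat <- vapply(1:4, function(k) {
    dl <- draws_of(fit, sprintf("beta[1,%d]", k))
    dr <- unlist(dl)
    mcse <- sd(dr) / sqrt(length(dr))
    (mean(dr) - ols[k + 1]) / mcse
  }, numeric(1))
  expect_lt(sum(zstat^2), qchisq(0.999, df = 4))
})
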