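# creeleffort

Weekly creel surveys measure recreational fishing pressure — effort, in
single-angler, single-day trips — along a coast where the decision to go
fishing is driven by weather, interrupted by tropical cyclones, and, in
2020, upended by a pandemic. `creeleffort` packages the three analyses this
system calls for, together with a synthetic-data generator with known
ground truth so every estimator can be validated by parameter recovery:

1. **Weather–effort model.** A Bayesian hierarchical regression of weekly
   log effort on four standardized covariates — effort-weighted
   precipitation, maximum temperature, and maximum wind, plus the weekly
   small-craft-advisory count — with varying intercepts and slopes by
   month, and a second-level regression that lets the temperature slope
   drift over the calendar year:

   ```
   y_i       ~ Normal(alpha_j(i) + sum_k beta_j(i),k * z_ik, sigma^2)
   beta_j,.  ~ MVN(mu_j, Sigma),   mu_j = (mu_1, gamma0 + gamma1 * z_month(j), mu_3, mu_4)
   alpha_j   ~ Normal(mu_alpha, sigma_alpha^2)
   ```

   Fit with JAGS (via `rjags`); convergence assessed with a split-chain
   rank-normalized Gelman–Rubin statistic (converged when max R-hat < 1.1).

2. **Tropical-cyclone recovery model.** For each storm, the five weeks of
   effort starting at landfall (or at the warning week, when landfall falls
   early in the next survey week) enter a varying-intercepts,
   varying-slopes regression of log effort on relative week 1–5, with the
   storm slopes regressed on Saffir–Simpson category at landfall
   (`b_k ~ Normal(delta0 + delta1 * category_k, tau^2)`), testing whether
   severer storms dig deeper holes and climb out of them faster.

3. **Pandemic comparison.** Monthly 2020 effort per region against the
   2015–2019 baseline (mean line, min–max envelope), expressed both as
   percent difference from baseline and percent of normal.

The generator emulates the study system: two coastal regions (east/west),
Monday-start 52-week survey years over 2015–2021, subtropical seasonal
weather (sinusoid + AR(1) temperature with winter-heavy variance,
zero-inflated gamma rain, Weibull wind), advisory counts scaled by forecast
zones, a 12-storm catalog with a fixed severity mix (six tropical storms,
two Cat-1, one Cat-2, one Cat-3, two Cat-4), a 70/30 weekend/weekday
within-week effort split, and monthly 2020 effort multipliers.

## Worked example

```r
library(creeleffort)
sim  <- simulate_survey(seed = 1)                      # synthetic survey, known truth
eff  <- aggregate_regions(sim$effort_area)             # areas -> east/west regions
rec  <- build_weekly_records(eff, sim$weekly_weather,
                             sim$advisories, sim$calendar, sim$storms)
kept <- exclusion_filter(rec)                          # drop warning/holiday/2020 weeks
east <- standardize(kept[kept$region == "east", ])
fit  <- fit_weather_model(build_weather_model(east), seed = 1)
print(fit)
#> Hierarchical weather-effort posterior (east region)
#>   3 chains, 6000 retained draws
#> R-hat over 85 parameters: max 1.0214 (g0); converged (max < 1.1)

head(subset(summarize_monthly_effects(fit), variable == "temperature"), 4)
#>    region    variable month mean  lower upper credible
#> 13   east temperature     1 0.22 0.0928  0.35     TRUE
#> 14   east temperature     2 0.17 0.0301  0.31     TRUE
#> 15   east temperature     3 0.15 0.0310  0.26     TRUE
#> 16   east temperature     4 0.12 0.0025  0.24     TRUE
```

A warm week in January raises log effort by about 0.22 standardized units
(credibly positive); the effect fades toward summer, and the second-level
month trend on the temperature slope is negative but not credible:

```r
temperature_month_trend(fit)$summary
#>   parameter   mean  lower  upper credible
#> 1    gamma0  0.110  0.034 0.1918     TRUE
#> 2    gamma1 -0.016 -0.035 0.0026    FALSE
```

Storm recovery and the pandemic year:

```r
tc <- fit_tc_model(build_tc_subset(eff, sim$storms, sim$calendar), seed = 1)
attr(classify_recovery(tc), "level2")
#>   parameter  mean  lower upper credible
#> 1    delta0 0.036 -0.064 0.130    FALSE
#> 2    delta1 0.022 -0.028 0.073    FALSE

subset(pandemic_summary(eff, sim$calendar), region == "east" & month %in% 3:4)
#>   region month effort_2020 baseline_mean baseline_min baseline_max pct_diff pct_of_normal
#> 3   east     3       67641         45551        35571        51155     48.5           148
#> 4   east     4      120030         60652        53669        66671     97.9           198
```

March–April 2020 effort runs roughly 50–100% above the pre-pandemic
baseline in this realization, while the generative multipliers for those
months are 1.75 (percentages vary with noise and with how many survey weeks
each year's calendar assigns to a month).

`run_pipeline(default_config(seed = 1))` executes the whole chain —
simulate, prepare, fit both regional weather models, fit the recovery
model, compare the pandemic year — and writes every table, an R-hat
report, a removal audit log, and summary figures to an output directory.

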