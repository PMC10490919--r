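#' Build the five-week post-landfall effort subset
#'
#' For each storm, extracts five consecutive region-weeks of effort from the
#' impacted region, starting at the storm's impact week (the landfall week,
#' or the preceding warning week when landfall falls on the Monday or
#' Tuesday of the next week so that the 36-hour-lead warning -- and the
#' collapse in effort -- came the week before). Effort is natural-log
#' transformed. The subset is taken from the unfiltered effort series:
#' warning weeks must be present here even though the weather model excludes
#' them.
#'
#' @param effort Regional weekly effort (`year`, `week`, `region`, `effort`).
#' @param storms Storm catalog.
#' @param calendar Survey calendar.
#' @param warning_lead_days Warning lead time in days (see
#'   [storm_impact_week()]).
#' @return Data frame `storm_id`, `category`, `region`, `relative_week`
#'   (1--5), `year`, `week`, `log_effort`, with exactly 5 rows per storm.
#' @export
build_tc_subset <- function(effort, storms, calendar, warning_lead_days = 2) {
  iw <- storm_impact_week(storms$landfall_date, calendar, warning_lead_days)
  rows <- lapply(seq_len(nrow(storms)), function(k) {
    if (is.na(iw[k]) || iw[k] + 4 > nrow(calendar)) {
      stop("storm ", storms$storm_id[k],
           " is too close to the end of the series for a 5-week window")
    }
    idx <- iw[k] + 0:4
    e <- effort[effort$region == storms$impacted_region[k], ]
    pos <- match(paste(calendar$year[idx], calendar$week[idx]),
                 paste(e$year, e$week))
    if (anyNA(pos)) {
      stop("effort series is missing post-landfall weeks for storm ",
           storms$storm_id[k])
    }
    data.frame(storm_id = storms$storm_id[k],
               category = storms$category[k],
               region = storms$impacted_region[k],
               relative_week = 1:5,
               year = e$year[pos], week = e$week[pos],
               log_effort = log(e$effort[pos]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specification for the effort-recovery model
#'
#' @param chains,iterations,burnin,thin,adapt MCMC schedule (same
#'   conventions as [weather_model_spec()]).
#' @param severity_slope Include the level-2 regression of recovery slope on
#'   storm category (`delta1`)? Must be `FALSE` when all storms share one
#'   category, where the slope is unidentified.
#' @param coef_sd,sigma_upper Diffuse-prior constants.
#' @return A list with class `"tc_model_spec"`.
#' @export
tc_model_spec <- function(chains = 3, iterations = 4000, burnin = 2000,
                          thin = 1, adapt = 500, severity_slope = TRUE,
                          coef_sd = 100, sigma_upper = 10) {
  if (chains < 2) stop("`chains` must be at least 2")
  if (burnin >= iterations) stop("`burnin` must be smaller than `iterations`")
  out <- list(chains = as.integer(chains), iterations = as.integer(iterations),
              burnin = as.integer(burnin), thin = as.integer(thin),
              adapt = as.integer(adapt), severity_slope = isTRUE(severity_slope),
              coef_sd = coef_sd, sigma_upper = sigma_upper)
  class(out) <- "tc_model_spec"
  out
}

tc_model_code <- function(spec) {
  slope_mean <- if (spec$severity_slope) "d0 + d1 * cat[k]" else "d0"
  d1_prior <- if (spec$severity_slope) "  d1 ~ dnorm(0, prec.coef)\n" else ""
  paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    "    y[i] ~ dnorm(a[s[i]] + b[s[i]] * w[i], tau.y)\n",
    "  }\n",
    "  for (k in 1:S) {\n",
    "    a[k] ~ dnorm(mu.a, tau.a)\n",
    "    b[k] ~ dnorm(", slope_mean, ", tau.b)\n",
    "  }\n",
    "  mu.a ~ dnorm(0, prec.coef)\n",
    "  d0 ~ dnorm(0, prec.coef)\n",
    d1_prior,
    "  sigma.a ~ dunif(0, sigma.upper)\n",
    "  tau.a <- pow(sigma.a, -2)\n",
    "  tau.b_sd ~ dunif(0, sigma.upper)\n",
    "  tau.b <- pow(tau.b_sd, -2)\n",
    "  sigma ~ dunif(0, sigma.upper)\n",
    "  tau.y <- pow(sigma, -2)\n",
    "}\n")
}

#' Fit the hierarchical effort-recovery model
#'
#' Varying-intercepts, varying-slopes regression of log effort on relative
#' week to landfall (1--5, uncentered), with one intercept and slope per
#' storm. Storm slopes are drawn from a normal whose mean is a simple linear
#' regression on storm severity (Saffir-Simpson category at landfall, 0 for
#' tropical storms), capturing the hypothesis that more severe storms dig a
#' deeper hole and recover faster week over week. Priors are diffuse.
#'
#' @param subset A [build_tc_subset()] table.
#' @param spec A [tc_model_spec()].
#' @param seed Integer seed.
#' @param quiet Suppress JAGS output?
#' @return A list of class `"tc_posterior"`: `samples`, `rhat`, `storms`
#'   (ids and categories in model order), `spec`, `retained`, `seed`.
#' @export
fit_tc_model <- function(subset, spec = tc_model_spec(), seed = 1,
                         quiet = TRUE) {
  ids <- unique(subset$storm_id)
  cat_of <- subset$category[match(ids, subset$storm_id)]
  if (spec$severity_slope && length(unique(cat_of)) < 2) {
    stop("all storms share one category: the severity slope is ",
         "unidentified; refit with `severity_slope = FALSE`")
  }
  dat <- list(y = subset$log_effort, w = subset$relative_week,
              s = match(subset$storm_id, ids), n = nrow(subset),
              S = length(ids), prec.coef = spec$coef_sd^-2,
              sigma.upper = spec$sigma_upper)
  if (spec$severity_slope) dat$cat <- cat_of
  inits <- lapply(seq_len(spec$chains), function(ch) {
    set.seed(seed * 100 + ch)
    ii <- list(a = stats::rnorm(dat$S, mean(dat$y), 0.5),
               b = stats::rnorm(dat$S, 0, 0.2),
               mu.a = stats::rnorm(1, mean(dat$y), 1),
               d0 = stats::rnorm(1, 0, 0.2),
               sigma = stats::runif(1, 0.05, 1),
               sigma.a = stats::runif(1, 0.05, 1),
               tau.b_sd = stats::runif(1, 0.05, 1),
               .RNG.name = "base::Mersenne-Twister",
               .RNG.seed = seed * 100 + ch)
    if (spec$severity_slope) ii$d1 <- stats::rnorm(1, 0, 0.1)
    ii
  })
  monitors <- c("a", "b", "mu.a", "d0", "sigma", "sigma.a", "tau.b_sd")
  if (spec$severity_slope) monitors <- c(monitors, "d1")
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(tc_model_code(spec)), data = dat,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = spec$adapt, quiet = quiet)
  stats::update(jm, n.iter = spec$burnin, progress.bar = "none")
  samples <- rjags::coda.samples(jm, variable.names = monitors,
                                 n.iter = spec$iterations - spec$burnin,
                                 thin = spec$thin, progress.bar = "none")
  rr <- rhat_report(samples)
  if (!rr$converged) {
    warning(sprintf("convergence not reached: max R-hat %.3f (%s)",
                    rr$max_rhat, rr$worst))
  }
  out <- list(samples = samples, rhat = rr,
              storms = data.frame(storm_id = ids, category = cat_of),
              spec = spec,
              retained = spec$chains *
                ((spec$iterations - spec$burnin) %/% spec$thin),
              seed = seed)
  class(out) <- "tc_posterior"
  out
}

#' Classify per-storm recovery slopes
#'
#' Flags a storm as showing a significant effort recovery when the 95%
#' credible interval of its weekly slope lies strictly above zero.
#'
#' @param posterior A [fit_tc_model()] result.
#' @param level Credible-interval mass.
#' @return Data frame `storm_id`, `category`, `slope_mean`, `lower`,
#'   `upper`, `significant_positive`, with the level-2 severity regression
#'   summary attached as attribute `"level2"`.
#' @export
classify_recovery <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "tc_posterior"))
  out <- do.call(rbind, lapply(seq_len(nrow(posterior$storms)), function(k) {
    d <- posterior_draws(posterior, sprintf("b[%d]", k))
    ci <- credible_interval(d, level)
    data.frame(storm_id = posterior$storms$storm_id[k],
               category = posterior$storms$category[k],
               slope_mean = mean(d), lower = ci$lower, upper = ci$upper,
               significant_positive = ci$lower > 0)
  }))
  rownames(out) <- NULL
  attr(out, "level2") <- tc_level2_summary(posterior, level)
  out
}

#' Level-2 severity regression summary
#'
#' Posterior summary of the intercept (`delta0`) and, when modeled, the
#' severity slope (`delta1`) of the regression of storm recovery slopes on
#' category.
#'
#' @param posterior A [fit_tc_model()] result.
#' @param level Credible-interval mass.
#' @return Data frame `parameter`, `mean`, `lower`, `upper`, `credible`.
#' @export
tc_level2_summary <- function(posterior, level = 0.95) {
  pars <- c(delta0 = "d0")
  if (posterior$spec$severity_slope) pars <- c(pars, delta1 = "d1")
  out <- do.call(rbind, Map(function(nm, par) {
    d <- posterior_draws(posterior, par)
    ci <- credible_interval(d, level)
    data.frame(parameter = nm, mean = mean(d), lower = ci$lower,
               upper = ci$upper, credible = ci$excludes_zero)
  }, names(pars), pars))
  rownames(out) <- NULL
  out
}

#' Independent per-storm least-squares recovery fits
#'
#' Ordinary least-squares regression of log effort on relative week fit to
#' each storm's five points separately (no pooling), with classical 95%
#' confidence intervals -- the unpooled counterpart of the hierarchical
#' slopes, exposed for comparison.
#'
#' @param subset A [build_tc_subset()] table.
#' @param level Confidence level.
#' @return Data frame `storm_id`, `category`, `slope`, `lower`, `upper`,
#'   `significant_positive`.
#' @export
tc_storm_ols <- function(subset, level = 0.95) {
  ids <- unique(subset$storm_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    d <- subset[subset$storm_id == id, ]
    fit <- stats::lm(log_effort ~ relative_week, data = d)
    ci <- stats::confint(fit, "relative_week", level = level)
    data.frame(storm_id = id, category = d$category[1],
               slope = unname(stats::coef(fit)["relative_week"]),
               lower = ci[1], upper = ci[2],
               significant_positive = ci[1] > 0)
  }))
  rownames(out) <- NULL
  out
}
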