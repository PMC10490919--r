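#' Specification of the hierarchical weather-effort model
#'
#' Constants, priors, and MCMC schedule for the varying-slopes regression of
#' weekly log effort on four standardized weather covariates with monthly
#' random intercepts and slopes. Priors are diffuse: Normal(0, sd 100) on
#' location hyperparameters, Uniform(0, 10) on the residual and
#' between-month intercept SDs, and an inverse-Wishart prior on the 4x4
#' coefficient covariance.
#'
#' Two parameterizations of the covariance prior are offered. The default
#' (`sigma_prior = "iw"`) is a conjugate inverse-Wishart with df = K+1 and a
#' fixed scale matrix `wishart_scale * I` matched to the magnitude of
#' standardized coefficients; being fully conjugate it mixes rapidly, so the
#' short desk-scale schedule converges. The alternative
#' (`sigma_prior = "scaled-iw"`) is the parameter-expanded scaled
#' inverse-Wishart (inverse-Wishart(K+1, I) core with uniform scale factors
#' xi); its redundant scale ridge mixes far more slowly and needs a schedule
#' on the order of the full published one.
#'
#' The default desk-scale schedule is 3 chains of 4,000 iterations with the
#' first half discarded as burn-in and no thinning. The published-scale
#' schedule (3 x 100,000, burn-in 30,000, thin 2, 105,000 retained draws) is
#' available by setting the arguments accordingly.
#'
#' @param chains Number of parallel chains (>= 2).
#' @param iterations Iterations per chain including burn-in.
#' @param burnin Burn-in iterations discarded per chain (< iterations).
#' @param thin Thinning interval applied after burn-in (>= 1).
#' @param adapt JAGS adaptation iterations.
#' @param n_months Number of month groups J (12; reduce only for degenerate
#'   checks).
#' @param month_trend Model the monthly temperature coefficient as a linear
#'   function of the centered month index (the second-level regression)? If
#'   `FALSE` all four coefficient means are month-exchangeable.
#' @param coef_sd Prior SD of location hyperparameters.
#' @param sigma_upper Upper bound of the uniform priors on SDs.
#' @param sigma_prior Covariance-prior parameterization: `"iw"` (conjugate,
#'   default) or `"scaled-iw"` (parameter-expanded).
#' @param wishart_scale Diagonal value of the fixed inverse-Wishart scale
#'   matrix under `sigma_prior = "iw"`; 0.01 corresponds to coefficient SDs
#'   of about 0.1 on the standardized scale.
#' @param xi_upper Upper bound of the uniform priors on the Wishart scale
#'   factors under `sigma_prior = "scaled-iw"`.
#' @return A list with class `"weather_model_spec"`.
#' @export
weather_model_spec <- function(chains = 3, iterations = 4000, burnin = 2000,
                               thin = 1, adapt = 500, n_months = 12,
                               month_trend = TRUE, coef_sd = 100,
                               sigma_upper = 10,
                               sigma_prior = c("iw", "scaled-iw"),
                               wishart_scale = 0.01, xi_upper = 100) {
  if (chains < 2) stop("`chains` must be at least 2")
  if (burnin >= iterations) stop("`burnin` must be smaller than `iterations`")
  if (thin < 1) stop("`thin` must be at least 1")
  out <- list(chains = as.integer(chains), iterations = as.integer(iterations),
              burnin = as.integer(burnin), thin = as.integer(thin),
              adapt = as.integer(adapt), n_months = as.integer(n_months),
              month_trend = isTRUE(month_trend), coef_sd = coef_sd,
              sigma_upper = sigma_upper,
              sigma_prior = match.arg(sigma_prior),
              wishart_scale = wishart_scale, xi_upper = xi_upper)
  class(out) <- "weather_model_spec"
  out
}

#' Retained-draw arithmetic of an MCMC schedule
#'
#' @param chains,iterations,burnin,thin Schedule; may also be given as a
#'   single `weather_model_spec` in `chains`.
#' @return Total retained draws: `chains * floor((iterations - burnin) / thin)`.
#' @examples
#' retained_draws(3, 100000, 30000, 2) # 105000
#' @export
retained_draws <- function(chains, iterations = NULL, burnin = NULL,
                           thin = NULL) {
  if (inherits(chains, "weather_model_spec")) {
    spec <- chains
    return(spec$chains * ((spec$iterations - spec$burnin) %/% spec$thin))
  }
  chains * ((iterations - burnin) %/% thin)
}

weather_model_code <- function(spec) {
  tail_block <- paste0(
    "  mu.alpha ~ dnorm(0, prec.coef)\n",
    "  sigma.alpha ~ dunif(0, sigma.upper)\n",
    "  tau.alpha <- pow(sigma.alpha, -2)\n",
    "  sigma ~ dunif(0, sigma.upper)\n",
    "  tau.y <- pow(sigma, -2)\n",
    "}\n")
  likelihood <- paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    "    mu.y[i] <- alpha[m[i]] + inprod(beta[m[i], 1:K], z[i, 1:K])\n",
    "    y[i] ~ dnorm(mu.y[i], tau.y)\n",
    "  }\n")
  if (spec$sigma_prior == "iw") {
    mu2 <- if (spec$month_trend) "g0 + g1 * zm[j]" else "mu.beta[2]"
    trend_block <- if (spec$month_trend) {
      "  g0 ~ dnorm(0, prec.coef)\n  g1 ~ dnorm(0, prec.coef)\n  mu.beta[2] <- g0\n"
    } else {
      "  mu.beta[2] ~ dnorm(0, prec.coef)\n"
    }
    paste0(
      likelihood,
      "  for (j in 1:J) {\n",
      "    alpha[j] ~ dnorm(mu.alpha, tau.alpha)\n",
      "    beta[j, 1:K] ~ dmnorm(mu.m[j, 1:K], Tau[1:K, 1:K])\n",
      "    mu.m[j, 1] <- mu.beta[1]\n",
      "    mu.m[j, 2] <- ", mu2, "\n",
      "    mu.m[j, 3] <- mu.beta[3]\n",
      "    mu.m[j, 4] <- mu.beta[4]\n",
      "  }\n",
      "  mu.beta[1] ~ dnorm(0, prec.coef)\n",
      trend_block,
      "  mu.beta[3] ~ dnorm(0, prec.coef)\n",
      "  mu.beta[4] ~ dnorm(0, prec.coef)\n",
      "  Tau[1:K, 1:K] ~ dwish(W[1:K, 1:K], wish.df)\n",
      "  Sigma[1:K, 1:K] <- inverse(Tau[1:K, 1:K])\n",
      tail_block)
  } else {
    mu2 <- if (spec$month_trend) "g0.raw + g1.raw * zm[j]" else "mu.b.raw[2]"
    trend_block <- if (spec$month_trend) {
      "  g0.raw ~ dnorm(0, prec.coef)\n  g1.raw ~ dnorm(0, prec.coef)\n  g0 <- xi[2] * g0.raw\n  g1 <- xi[2] * g1.raw\n  mu.beta[2] <- g0\n"
    } else {
      "  mu.beta[2] <- xi[2] * mu.b.raw[2]\n"
    }
    paste0(
      likelihood,
      "  for (j in 1:J) {\n",
      "    alpha[j] ~ dnorm(mu.alpha, tau.alpha)\n",
      "    beta.raw[j, 1:K] ~ dmnorm(mu.raw[j, 1:K], Tau.raw[1:K, 1:K])\n",
      "    mu.raw[j, 1] <- mu.b.raw[1]\n",
      "    mu.raw[j, 2] <- ", mu2, "\n",
      "    mu.raw[j, 3] <- mu.b.raw[3]\n",
      "    mu.raw[j, 4] <- mu.b.raw[4]\n",
      "    for (k in 1:K) { beta[j, k] <- xi[k] * beta.raw[j, k] }\n",
      "  }\n",
      "  for (k in 1:K) {\n",
      "    mu.b.raw[k] ~ dnorm(0, prec.coef)\n",
      "    xi[k] ~ dunif(0, xi.upper)\n",
      "  }\n",
      "  mu.beta[1] <- xi[1] * mu.b.raw[1]\n",
      trend_block,
      "  mu.beta[3] <- xi[3] * mu.b.raw[3]\n",
      "  mu.beta[4] <- xi[4] * mu.b.raw[4]\n",
      "  Tau.raw[1:K, 1:K] ~ dwish(W[1:K, 1:K], wish.df)\n",
      "  Sigma.raw[1:K, 1:K] <- inverse(Tau.raw[1:K, 1:K])\n",
      "  for (k in 1:K) { for (l in 1:K) {\n",
      "    Sigma[k, l] <- xi[k] * xi[l] * Sigma.raw[k, l]\n",
      "  } }\n",
      tail_block)
  }
}

#' Build the hierarchical weather-effort model
#'
#' Assembles the JAGS model and data for the regression of weekly log effort
#' on the four standardized covariates (precipitation, temperature, wind,
#' small-craft advisories). Coefficients vary by month and are drawn from a
#' multivariate normal whose temperature component follows the second-level
#' month trend (when `month_trend` is on); intercepts are exchangeable
#' normal across months. The centered month index `z_month(j) = j - (J+1)/2`
#' feeds the trend.
#'
#' @param design A `design_table` from [standardize()].
#' @param spec A [weather_model_spec()].
#' @return A list of class `"weather_model"`: `code` (JAGS model string),
#'   `data`, `monitors`, `spec`, plus the design attributes.
#' @export
build_weather_model <- function(design, spec = weather_model_spec()) {
  J <- spec$n_months
  K <- 4L
  months <- sort(unique(design$month))
  missing_m <- setdiff(seq_len(J), months)
  if (length(missing_m)) {
    stop("no data for month(s): ", paste(missing_m, collapse = ", "))
  }
  if (any(!design$month %in% seq_len(J))) {
    stop("month labels outside 1..", J)
  }
  z <- as.matrix(design[, c("z_precip", "z_temp", "z_wind", "z_sca")])
  dat <- list(y = design$log_effort, z = z, m = as.integer(design$month),
              n = nrow(design), J = J, K = K,
              wish.df = K + 1,
              prec.coef = spec$coef_sd^-2,
              sigma.upper = spec$sigma_upper)
  if (spec$sigma_prior == "iw") {
    dat$W <- spec$wishart_scale * diag(K)
  } else {
    dat$W <- diag(K)
    dat$xi.upper <- spec$xi_upper
  }
  if (spec$month_trend) {
    dat$zm <- seq_len(J) - (J + 1) / 2
  }
  monitors <- c("alpha", "beta", "mu.beta", "Sigma", "sigma",
                "mu.alpha", "sigma.alpha")
  if (spec$month_trend) monitors <- c(monitors, "g0", "g1")
  out <- list(code = weather_model_code(spec), data = dat,
              monitors = monitors, spec = spec,
              center = attr(design, "center"), scale = attr(design, "scale"),
              region = attr(design, "region"))
  class(out) <- "weather_model"
  out
}

weather_model_inits <- function(model, seed) {
  J <- model$data$J; K <- model$data$K
  ybar <- mean(model$data$y)
  scaled <- model$spec$sigma_prior == "scaled-iw"
  lapply(seq_len(model$spec$chains), function(ch) {
    set.seed(seed * 100 + ch)
    inits <- list(
      alpha = stats::rnorm(J, ybar, 0.5),
      mu.alpha = stats::rnorm(1, ybar, 1),
      sigma = stats::runif(1, 0.05, 1),
      sigma.alpha = stats::runif(1, 0.05, 1),
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = seed * 100 + ch
    )
    if (scaled) {
      inits$beta.raw <- matrix(stats::rnorm(J * K, 0, 0.3), J, K)
      inits$mu.b.raw <- stats::rnorm(K, 0, 0.3)
      inits$xi <- stats::runif(K, 0.5, 2)
      if (model$spec$month_trend) {
        inits$g0.raw <- stats::rnorm(1, 0, 0.3)
        inits$g1.raw <- stats::rnorm(1, 0, 0.1)
      }
    } else {
      inits$beta <- matrix(stats::rnorm(J * K, 0, 0.1), J, K)
      if (model$spec$month_trend) {
        inits$mu.beta <- c(stats::rnorm(1, 0, 0.1), NA,
                           stats::rnorm(2, 0, 0.1))
        inits$g0 <- stats::rnorm(1, 0, 0.1)
        inits$g1 <- stats::rnorm(1, 0, 0.05)
      } else {
        inits$mu.beta <- stats::rnorm(K, 0, 0.1)
      }
    }
    inits
  })
}

#' Fit the hierarchical weather-effort model by MCMC
#'
#' Runs the configured schedule in JAGS with over-dispersed chain starting
#' values derived from `seed`, discards the burn-in, applies thinning, and
#' computes the split-chain rank-normalized Gelman-Rubin statistic for every
#' monitored parameter. A convergence warning (not an error) is raised if
#' any R-hat is 1.1 or above.
#'
#' @param model A [build_weather_model()] object.
#' @param seed Integer seed controlling chain initial values and RNG states.
#' @param quiet Suppress JAGS progress output?
#' @return A list of class `"weather_posterior"`: `samples` (`mcmc.list`),
#'   `rhat` (an `rhat_report`), `retained`, `spec`, `region`, `seed`.
#' @export
fit_weather_model <- function(model, seed = 1, quiet = TRUE) {
  stopifnot(inherits(model, "weather_model"))
  spec <- model$spec
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(model$code), data = model$data,
                          inits = weather_model_inits(model, seed),
                          n.chains = spec$chains, n.adapt = spec$adapt,
                          quiet = quiet)
  stats::update(jm, n.iter = spec$burnin, progress.bar = "none")
  samples <- rjags::coda.samples(jm, variable.names = model$monitors,
                                 n.iter = spec$iterations - spec$burnin,
                                 thin = spec$thin, progress.bar = "none")
  rr <- rhat_report(samples)
  if (!rr$converged) {
    warning(sprintf("convergence not reached: max R-hat %.3f (%s)",
                    rr$max_rhat, rr$worst))
  }
  out <- list(samples = samples, rhat = rr,
              retained = retained_draws(spec), spec = spec,
              region = model$region, center = model$center,
              scale = model$scale, seed = seed)
  class(out) <- "weather_posterior"
  out
}

#' @export
print.weather_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical weather-effort posterior (%s region)\n",
              x$region %||% "unknown"))
  cat(sprintf("  %d chains, %d retained draws\n", x$spec$chains, x$retained))
  print(x$rhat)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

posterior_draws <- function(posterior, par) {
  have <- colnames(posterior$samples[[1]])
  if (!par %in% have) {
    # JAGS names a length-1 vector node without the [1] suffix
    bare <- sub("\\[1\\]$", "", par)
    if (bare %in% have) par <- bare else stop("no draws for parameter ", par)
  }
  unlist(lapply(posterior$samples, function(ch) as.numeric(ch[, par])),
         use.names = FALSE)
}

#' Posterior summaries of the 48 monthly weather effects
#'
#' One row per (covariate, month): posterior mean, central 95% credible
#' interval, and whether the interval excludes zero (a "credible" monthly
#' effect). Two regional fits give the full set of 96 candidate effects.
#'
#' @param posterior A [fit_weather_model()] result.
#' @param region Region label for the output (defaults to the fit's region).
#' @param level Credible-interval mass.
#' @return Data frame `region`, `variable`, `month`, `mean`, `lower`,
#'   `upper`, `credible` with `4 * J` rows.
#' @export
summarize_monthly_effects <- function(posterior, region = NULL, level = 0.95) {
  stopifnot(inherits(posterior, "weather_posterior"))
  region <- region %||% posterior$region %||% "unknown"
  vars <- c("precipitation", "temperature", "wind", "sca")
  J <- posterior$spec$n_months
  rows <- lapply(seq_along(vars), function(k) {
    do.call(rbind, lapply(seq_len(J), function(j) {
      d <- posterior_draws(posterior, sprintf("beta[%d,%d]", j, k))
      ci <- credible_interval(d, level)
      data.frame(region = region, variable = vars[k], month = j,
                 mean = mean(d), lower = ci$lower, upper = ci$upper,
                 credible = ci$excludes_zero)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Second-level month trend of the temperature coefficient
#'
#' Summarizes the intercept and slope of the regression of the monthly
#' temperature coefficient on the centered month index, plus the fitted
#' trend line evaluated at each month (the line drawn through the monthly
#' temperature effects).
#'
#' @param posterior A [fit_weather_model()] result from a `month_trend`
#'   model.
#' @param level Credible-interval mass.
#' @return A list: `summary` (data frame for `gamma0`, `gamma1` with mean,
#'   interval, and credible flag) and `line` (data frame `month`, `value`
#'   of the posterior-mean trend line).
#' @export
temperature_month_trend <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "weather_posterior"))
  if (!posterior$spec$month_trend) {
    stop("model was fit without the month trend")
  }
  g0 <- posterior_draws(posterior, "g0")
  g1 <- posterior_draws(posterior, "g1")
  summ <- do.call(rbind, Map(function(nm, d) {
    ci <- credible_interval(d, level)
    data.frame(parameter = nm, mean = mean(d), lower = ci$lower,
               upper = ci$upper, credible = ci$excludes_zero)
  }, c("gamma0", "gamma1"), list(g0, g1)))
  rownames(summ) <- NULL
  J <- posterior$spec$n_months
  zm <- seq_len(J) - (J + 1) / 2
  list(summary = summ,
       line = data.frame(month = seq_len(J),
                         value = mean(g0) + mean(g1) * zm))
}
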