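#' Generative ground-truth parameters for the synthetic effort model
#'
#' Bundles every parameter of the generative model that the analyses try to
#' recover: monthly log-effort intercepts, monthly standardized coefficients
#' for (precipitation, temperature, wind, advisory), their population mean
#' and covariance, the month-trend parameters of the temperature
#' coefficient, residual SD, storm disturbance parameters, and monthly
#' pandemic multipliers.
#'
#' The monthly mean coefficient vector is
#' `mu_j = (mu_precip, gamma0 + gamma1 * (j - 6.5), mu_wind, mu_sca)`: the
#' temperature coefficient declines over the calendar year (strongly positive
#' in winter, near zero by autumn) while the other three are
#' month-exchangeable. If `beta` is not supplied it is either set to `mu_j`
#' exactly (no seed) or drawn from `MVN(mu_j, Sigma)` (with a seed), and the
#' realized matrix is stored so recovery tests know the truth.
#'
#' @param seed Optional integer seed used to draw `beta` from its
#'   population distribution; if `NULL`, `beta` equals the monthly means.
#' @param alpha Numeric length-12 vector of monthly log-effort intercepts.
#' @param mu_precip,mu_wind,mu_sca Population-mean standardized coefficients.
#' @param gamma0,gamma1 Intercept and slope of the temperature coefficient
#'   against the centered month index `j - 6.5`.
#' @param Sigma 4x4 symmetric positive-definite coefficient covariance.
#' @param beta Optional 12x4 matrix of monthly coefficients overriding the
#'   draw.
#' @param sigma_resid Residual SD of log effort (>= 0; 0 gives the
#'   deterministic limit).
#' @param storm_dip Log-scale effort dip per unit of (1 + category) in the
#'   first impact week.
#' @param storm_recovery_per_cat Weekly recovery slope per unit of
#'   (1 + category).
#' @param pandemic_mult Length-12 positive multipliers applied to 2020
#'   effort by month; defaults follow the observed 2020 pattern (normal
#'   Jan--Feb, large spring and August surges, a slight autumn deficit).
#' @return A list with class `"truth_bundle"`.
#' @export
truth_bundle <- function(seed = NULL,
                         alpha = log(12000) +
                           0.5 * cos(2 * pi * ((1:12) - 6.5) / 12),
                         mu_precip = -0.06,
                         mu_wind = -0.06,
                         mu_sca = -0.03,
                         gamma0 = 0.10,
                         gamma1 = -0.02,
                         Sigma = diag(c(0.04, 0.06, 0.04, 0.03)^2),
                         beta = NULL,
                         sigma_resid = 0.2,
                         storm_dip = 0.25,
                         storm_recovery_per_cat = 0.05,
                         pandemic_mult = c(1, 1, 1.75, 1.75, 1.4, 1,
                                           1, 1.5, 1, 0.9, 1, 1)) {
  stopifnot(length(alpha) == 12, length(pandemic_mult) == 12)
  if (!isTRUE(all.equal(Sigma, t(Sigma))) ||
      any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("`Sigma` must be symmetric positive-definite")
  }
  if (sigma_resid < 0) stop("`sigma_resid` must be non-negative")
  if (any(pandemic_mult <= 0)) stop("`pandemic_mult` must be positive")
  zm <- (1:12) - 6.5
  mu_month <- cbind(precip = rep(mu_precip, 12),
                    temp = gamma0 + gamma1 * zm,
                    wind = rep(mu_wind, 12),
                    sca = rep(mu_sca, 12))
  if (is.null(beta)) {
    if (is.null(seed)) {
      beta <- mu_month
    } else {
      set.seed(seed)
      L <- t(chol(Sigma))
      beta <- t(apply(mu_month, 1, function(m) m + as.numeric(L %*% stats::rnorm(4))))
      colnames(beta) <- colnames(mu_month)
    }
  } else {
    beta <- as.matrix(beta)
    stopifnot(nrow(beta) == 12, ncol(beta) == 4)
    colnames(beta) <- colnames(mu_month)
  }
  out <- list(alpha = alpha, beta = beta,
              mu = c(precip = mu_precip, temp = gamma0, wind = mu_wind,
                     sca = mu_sca),
              Sigma = Sigma, gamma0 = gamma0, gamma1 = gamma1,
              sigma_resid = sigma_resid, storm_dip = storm_dip,
              storm_recovery_per_cat = storm_recovery_per_cat,
              pandemic_mult = pandemic_mult)
  class(out) <- "truth_bundle"
  out
}

#' Write a truth bundle to a YAML file
#'
#' @param truth A [truth_bundle()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_bundle"))
  x <- unclass(truth)
  x$beta <- apply(truth$beta, 1, as.numeric, simplify = FALSE)
  x$Sigma <- apply(truth$Sigma, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(x, path)
  invisible(path)
}
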