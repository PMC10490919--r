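#' Split-chain rank-normalized Gelman-Rubin statistic
#'
#' Potential scale reduction factor comparing between- and within-chain
#' variance. Each chain is split in half (so slow trends inside a chain
#' register as disagreement between chains) and draws are rank-normalized
#' across the pooled sample before the classic between/within variance ratio
#' is formed, making the statistic invariant to monotone transformations of
#' the parameter. Values below 1.1 are conventionally taken to indicate
#' convergence; the rank-normalized variant can dip slightly below 1.
#'
#' @param chains Draws for one parameter: an `mcmc.list`, a matrix with one
#'   column per chain, or a list of equal-length numeric vectors.
#' @param split Split each chain in half first?
#' @param rank_normalize Rank-normalize the pooled draws first?
#' @return The scalar R-hat; `NA` (with a warning) when the draws are
#'   constant and the ratio is undefined.
#' @examples
#' set.seed(1)
#' gelman_rubin(matrix(rnorm(2000), ncol = 2)) # ~1
#' @export
gelman_rubin <- function(chains, split = TRUE, rank_normalize = TRUE) {
  x <- as_chain_matrix(chains)
  if (ncol(x) < 2) stop("need at least 2 chains")
  if (nrow(x) < 4) stop("need at least 4 draws per chain")
  if (split) {
    n2 <- floor(nrow(x) / 2)
    x <- cbind(x[seq_len(n2), , drop = FALSE],
               x[nrow(x) - n2 + seq_len(n2), , drop = FALSE])
  }
  if (rank_normalize) {
    r <- rank(x, ties.method = "average")
    z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
    x <- matrix(z, nrow(x), ncol(x))
  }
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(colMeans(x))
  if (!is.finite(W) || W == 0) {
    warning("constant chains: R-hat is undefined")
    return(NA_real_)
  }
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

as_chain_matrix <- function(chains) {
  if (inherits(chains, "mcmc.list")) {
    chains <- lapply(chains, as.numeric)
  }
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1) {
      stop("all chains must have the same length")
    }
    chains <- do.call(cbind, chains)
  }
  as.matrix(chains)
}

#' Per-parameter convergence report
#'
#' Computes [gelman_rubin()] for every monitored parameter of an MCMC fit
#' and flags convergence by the conventional max R-hat < 1.1 rule.
#'
#' @param samples An `mcmc.list` (as returned by `rjags`) or a posterior
#'   object with a `$samples` element.
#' @return A list of class `"rhat_report"`: `rhat` (named vector), `max_rhat`,
#'   `worst` (parameter attaining the max), `converged`.
#' @export
rhat_report <- function(samples) {
  if (!inherits(samples, "mcmc.list") && !is.null(samples$samples)) {
    samples <- samples$samples
  }
  stopifnot(inherits(samples, "mcmc.list"))
  pars <- colnames(samples[[1]])
  rhat <- vapply(pars, function(p) {
    gelman_rubin(sapply(samples, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  finite <- rhat[is.finite(rhat)]
  out <- list(rhat = rhat,
              max_rhat = if (length(finite)) max(finite) else NA_real_,
              worst = if (length(finite)) names(finite)[which.max(finite)] else NA_character_,
              converged = length(finite) > 0 && max(finite) < 1.1)
  class(out) <- "rhat_report"
  out
}

#' @export
print.rhat_report <- function(x, ...) {
  cat(sprintf("R-hat over %d parameters: max %.4f (%s); %s\n",
              length(x$rhat), x$max_rhat, x$worst,
              if (x$converged) "converged (max < 1.1)" else "NOT converged"))
  invisible(x)
}

#' Central credible interval from posterior draws
#'
#' Equal-tailed interval from the empirical quantiles (linear-interpolation
#' convention, `stats::quantile` type 7).
#'
#' @param draws Numeric vector of posterior draws (length >= 2).
#' @param level Interval mass, default 0.95.
#' @return A list: `lower`, `upper`, `excludes_zero`.
#' @examples
#' credible_interval(1:100)
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 2) stop("need at least 2 draws")
  stopifnot(level > 0, level < 1)
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  list(lower = q[1], upper = q[2],
       excludes_zero = q[1] > 0 || q[2] < 0)
}
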