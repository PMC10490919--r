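# Shared fixtures, built once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Full default synthetic survey: two regions, storms, pandemic.
sim_full <- function() memo("sim_full", function() simulate_survey(seed = 11))

# One region, pure regression process (no storms, no pandemic), known truth.
sim_plain <- function() memo("sim_plain", function() {
  truth <- truth_bundle(seed = 42)
  sim <- simulate_survey(seed = 5, truth = truth, storms = NA,
                         pandemic = FALSE, regions = "east",
                         zones_per_region = c(east = 7))
  sim$records <- build_weekly_records(sim$effort, sim$weekly_weather,
                                      sim$advisories, sim$calendar)
  sim$design <- standardize(sim$records)
  sim
})

uniform_weights <- function() do.call(effort_weights, as.list(rep(1 / 7, 7)))

# MCSE from pooled chains using the effective sample size.
mcse_eff <- function(chains_list) {
  dr <- unlist(chains_list, use.names = FALSE)
  ess <- coda::effectiveSize(coda::mcmc.list(lapply(chains_list, coda::mcmc)))
  stats::sd(dr) / sqrt(ess)
}

draws_of <- function(posterior, par) {
  have <- colnames(posterior$samples[[1]])
  if (!par %in% have) par <- sub("\\[1\\]$", "", par)
  lapply(posterior$samples, function(ch) as.numeric(as.matrix(ch)[, par]))
}
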