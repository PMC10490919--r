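#' Default end-to-end pipeline configuration
#'
#' @param seed Master seed for simulation and the MCMC fits.
#' @param start_year,end_year Study years.
#' @param out_dir Output directory.
#' @param chains,iterations,burnin,thin MCMC schedule for both models.
#' @param regions Regions to analyze.
#' @param save_draws Persist full posterior draw tables (CSV; large)?
#' @param make_plots Write summary figures (requires ggplot2)?
#' @return A named list.
#' @export
default_config <- function(seed = 1, start_year = 2015, end_year = 2021,
                           out_dir = tempfile("creeleffort-run-"),
                           chains = 3, iterations = 4000, burnin = 2000,
                           thin = 1, regions = c("east", "west"),
                           save_draws = FALSE, make_plots = TRUE) {
  list(seed = seed, start_year = start_year, end_year = end_year,
       out_dir = out_dir, chains = chains, iterations = iterations,
       burnin = burnin, thin = thin, regions = regions,
       save_draws = save_draws, make_plots = make_plots)
}

#' Read a pipeline configuration from YAML
#'
#' Any field omitted from the file keeps its [default_config()] value.
#'
#' @param path YAML file path.
#' @return A config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg[names(user)] <- user
  cfg
}

pipeline_stage <- function(name, expr, log) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full simulate-prepare-fit-report pipeline
#'
#' Executes simulate, prep, the weather-effort model per region, the
#' effort-recovery model, and the pandemic comparison; writes every table,
#' an R-hat report, a removal audit log, and (optionally) summary figures
#' under `config$out_dir`. Every filter decision and seed is logged to
#' `pipeline.log`.
#'
#' @param config A list from [default_config()] or [read_config()].
#' @return Invisibly, a list with the simulation, design tables, posteriors,
#'   effect tables, recovery classification, and pandemic summary.
#' @export
run_pipeline <- function(config = default_config()) {
  if (config$chains < 2) stop("config error: `chains` must be at least 2")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "pipeline.log")
  log <- function(msg) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = logfile, append = TRUE)
  }
  log(sprintf("seed %d; years %d-%d", config$seed, config$start_year,
              config$end_year))

  sim <- pipeline_stage("simulate", {
    s <- simulate_survey(config$start_year, config$end_year,
                         seed = config$seed)
    write_survey(s, file.path(config$out_dir, "inputs"))
    s
  }, log)

  prepped <- pipeline_stage("prep", {
    eff_region <- aggregate_regions(sim$effort_area)
    rec <- build_weekly_records(eff_region, sim$weekly_weather,
                                sim$advisories, sim$calendar, sim$storms)
    utils::write.csv(rec, file.path(config$out_dir, "weekly_records.csv"),
                     row.names = FALSE)
    kept <- exclusion_filter(rec)
    audit <- attr(kept, "audit")
    utils::write.csv(audit, file.path(config$out_dir, "removal_audit.csv"),
                     row.names = FALSE)
    for (i in seq_len(nrow(audit))) {
      log(sprintf("removed %s %d-%02d (%s)", audit$region[i], audit$year[i],
                  audit$week[i], audit$reason[i]))
    }
    designs <- lapply(config$regions, function(rg) {
      d <- standardize(kept[kept$region == rg, ])
      utils::write.csv(as.data.frame(d),
                       file.path(config$out_dir,
                                 sprintf("design_%s.csv", rg)),
                       row.names = FALSE)
      yaml::write_yaml(list(center = as.list(attr(d, "center")),
                            scale = as.list(attr(d, "scale"))),
                       file.path(config$out_dir,
                                 sprintf("design_%s_scaling.yml", rg)))
      d
    })
    names(designs) <- config$regions
    list(records = rec, kept = kept, designs = designs,
         effort = eff_region)
  }, log)

  spec <- weather_model_spec(chains = config$chains,
                             iterations = config$iterations,
                             burnin = config$burnin, thin = config$thin)
  fits <- pipeline_stage("fit-weather", {
    lapply(config$regions, function(rg) {
      log(sprintf("fitting weather model for %s (seed %d)", rg, config$seed))
      fit_weather_model(build_weather_model(prepped$designs[[rg]], spec),
                        seed = config$seed)
    })
  }, log)
  names(fits) <- config$regions

  effects <- pipeline_stage("summarize-weather", {
    eff <- do.call(rbind, lapply(config$regions, function(rg) {
      summarize_monthly_effects(fits[[rg]], region = rg)
    }))
    utils::write.csv(eff, file.path(config$out_dir, "monthly_effects.csv"),
                     row.names = FALSE)
    trends <- lapply(config$regions, function(rg) {
      tr <- temperature_month_trend(fits[[rg]])
      utils::write.csv(tr$summary,
                       file.path(config$out_dir,
                                 sprintf("temperature_trend_%s.csv", rg)),
                       row.names = FALSE)
      tr
    })
    names(trends) <- config$regions
    rhat <- do.call(rbind, lapply(config$regions, function(rg) {
      data.frame(region = rg, parameter = names(fits[[rg]]$rhat$rhat),
                 rhat = unname(fits[[rg]]$rhat$rhat))
    }))
    utils::write.csv(rhat, file.path(config$out_dir, "rhat_report.csv"),
                     row.names = FALSE)
    if (config$save_draws) {
      for (rg in config$regions) {
        utils::write.csv(as.data.frame(as.matrix(fits[[rg]]$samples)),
                         file.path(config$out_dir,
                                   sprintf("draws_%s.csv", rg)),
                         row.names = FALSE)
      }
    }
    list(effects = eff, trends = trends, rhat = rhat)
  }, log)

  tc <- pipeline_stage("fit-tc", {
    subset <- build_tc_subset(prepped$effort, sim$storms, sim$calendar)
    utils::write.csv(subset, file.path(config$out_dir, "tc_subset.csv"),
                     row.names = FALSE)
    post <- fit_tc_model(subset,
                         tc_model_spec(chains = config$chains,
                                       iterations = config$iterations,
                                       burnin = config$burnin,
                                       thin = config$thin),
                         seed = config$seed)
    cls <- classify_recovery(post)
    utils::write.csv(cls, file.path(config$out_dir, "tc_slopes.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(cls, "level2"),
                     file.path(config$out_dir, "tc_severity_regression.csv"),
                     row.names = FALSE)
    list(subset = subset, posterior = post, classification = cls)
  }, log)

  pand <- pipeline_stage("pandemic", {
    p <- pandemic_summary(prepped$effort, sim$calendar, config$regions)
    utils::write.csv(p, file.path(config$out_dir, "pandemic_summary.csv"),
                     row.names = FALSE)
    p
  }, log)

  if (isTRUE(config$make_plots) && requireNamespace("ggplot2", quietly = TRUE)) {
    pipeline_stage("plots", {
      ggplot2::ggsave(file.path(config$out_dir, "fig_monthly_effects.pdf"),
                      plot_monthly_effects(effects$effects,
                                           effects$trends),
                      width = 9, height = 6)
      ggplot2::ggsave(file.path(config$out_dir, "fig_tc_recovery.pdf"),
                      plot_tc_recovery(tc$subset, tc$classification),
                      width = 9, height = 6)
      ggplot2::ggsave(file.path(config$out_dir, "fig_pandemic.pdf"),
                      plot_pandemic(pand), width = 9, height = 4)
      NULL
    }, log)
  }
  log("done")
  invisible(list(sim = sim, prep = prepped, weather = fits,
                 effects = effects, tc = tc, pandemic = pand,
                 out_dir = config$out_dir))
}
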