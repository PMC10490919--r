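needs_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
}

#' Plot monthly weather-effect estimates
#'
#' Point-and-interval panels of the standardized monthly effects by region
#' and covariate, coloring effects whose 95% interval excludes zero, with
#' the second-level trend line drawn through the temperature panels.
#'
#' @param effects Stacked [summarize_monthly_effects()] tables.
#' @param trends Optional named list (by region) of
#'   [temperature_month_trend()] results.
#' @return A ggplot object.
#' @export
plot_monthly_effects <- function(effects, trends = NULL) {
  needs_ggplot2()
  p <- ggplot2::ggplot(effects,
                       ggplot2::aes(x = .data$month, y = .data$mean,
                                    color = .data$credible)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper), size = 0.3) +
    ggplot2::facet_grid(variable ~ region) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "steelblue"),
                                guide = "none") +
    ggplot2::scale_x_continuous(breaks = seq(1, 12, 2)) +
    ggplot2::labs(x = "Month", y = "Standardized monthly effect") +
    ggplot2::theme_bw()
  if (!is.null(trends)) {
    ln <- do.call(rbind, lapply(names(trends), function(rg) {
      data.frame(region = rg, variable = "temperature",
                 trends[[rg]]$line)
    }))
    p <- p + ggplot2::geom_line(data = ln,
                                ggplot2::aes(x = .data$month,
                                             y = .data$value),
                                inherit.aes = FALSE, color = "black")
  }
  p
}

#' Plot post-landfall effort recovery by storm
#'
#' Log-effort points for the five weeks after each storm with the
#' posterior-mean recovery line, red where the slope's interval lies above
#' zero.
#'
#' @param subset A [build_tc_subset()] table.
#' @param classification A [classify_recovery()] table.
#' @return A ggplot object.
#' @export
plot_tc_recovery <- function(subset, classification) {
  needs_ggplot2()
  sub <- merge(subset, classification[, c("storm_id", "slope_mean",
                                          "significant_positive")],
               by = "storm_id")
  means <- stats::aggregate(log_effort ~ storm_id, data = subset, FUN = mean)
  names(means)[2] <- "mean_log_effort"
  sub <- merge(sub, means, by = "storm_id")
  sub$fit <- sub$mean_log_effort +
    sub$slope_mean * (sub$relative_week - 3)
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$relative_week,
                                    y = .data$log_effort)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit,
                                    color = .data$significant_positive)) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "steelblue"),
                                guide = "none") +
    ggplot2::facet_wrap(~storm_id, scales = "free_y") +
    ggplot2::labs(x = "Relative week to landfall", y = "log(effort)") +
    ggplot2::theme_bw()
}

#' Plot pandemic-year effort against the pre-pandemic envelope
#'
#' Monthly 2020 effort over the 2015--2019 mean line and min/max band, by
#' region.
#'
#' @param summary A [pandemic_summary()] table.
#' @return A ggplot object.
#' @export
plot_pandemic <- function(summary) {
  needs_ggplot2()
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$month)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$baseline_min,
                                      ymax = .data$baseline_max),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline_mean),
                       color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$effort_2020),
                       color = "firebrick") +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_x_continuous(breaks = seq(1, 12, 2)) +
    ggplot2::labs(x = "Month", y = "Monthly effort (trips)") +
    ggplot2::theme_bw()
}
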