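#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot circadian RR profiles with prediction bands
#'
#' Draws the model's 24 h RR profile (with the normal-theory prediction
#' band) for one or more sex/age combinations.
#'
#' @param coefs A [circadian_coefficients] object.
#' @param sex Sexes to draw (default both).
#' @param age Ages in years to draw (default 35).
#' @param level Band coverage (default 0.95).
#' @return A ggplot object.
#' @export
plot_circadian_profile <- function(coefs, sex = c(0, 1), age = 35, level = 0.95) {
  grid <- tidyr::expand_grid(
    sex = sex, age = age,
    hour = seq(0, 24, by = 0.1)
  )
  band <- prediction_band(coefs, grid$sex, grid$age, grid$hour, level = level)
  grid <- dplyr::bind_cols(grid, band) |>
    dplyr::mutate(
      profile = sprintf("%s, %g y", ifelse(.data$sex == 1, "male", "female"), .data$age)
    )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$hour, y = .data$fit)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lwr, ymax = .data$upr, fill = .data$profile),
      alpha = 0.15
    ) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$profile)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::labs(
      x = "Time of day (h)", y = "RR interval (ms)",
      colour = NULL, fill = NULL,
      title = sprintf("Circadian RR profile with %g%% prediction band", 100 * level)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn visual_predictive_check Ribbon plot of observed vs simulated
#'   per-hour RR percentiles.
#' @param object An `rr_vpc` table.
#' @param ... Unused.
#' @export
autoplot.rr_vpc <- function(object, ...) {
  d <- dplyr::mutate(object, hour = as.numeric(as.character(.data$hour_bin)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hour)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$sim_p5, ymax = .data$sim_p95),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_p50), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_p50)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$obs_p5, ymax = .data$obs_p95), width = 0.3
    ) +
    ggplot2::labs(
      x = "Time of day (h)", y = "RR interval (ms)",
      title = "Visual predictive check",
      subtitle = "points/bars: observed median and 5-95% range; ribbon: simulated"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn delta_qtcf_single_baseline Mean +/- SD plot of a delta-QTcF
#'   summary by time of day.
#' @param object A `qtcf_summary` table.
#' @param ... Unused.
#' @export
autoplot.qtcf_summary <- function(object, ...) {
  lab <- switch(attr(object, "correction"),
    single_point = "single-point baseline correction",
    individualized = "individualised baseline correction",
    "baseline correction"
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$hour, y = .data$mean_delta_ms)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_delta_ms - .data$sd_delta_ms,
        ymax = .data$mean_delta_ms + .data$sd_delta_ms
      ),
      width = 0.5
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Time of day (h)", y = expression(Delta * "QTcF (ms)"),
      title = sprintf("Drug-induced QTcF change (%s)", lab),
      subtitle = "mean +/- SD across subjects and trial replicates"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_circadian_model Fitted circadian profiles (per sex, at
#'   the cohort mean age) overlaid on hourly medians of the observations.
#' @param object A `circadian_fit`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.circadian_fit <- function(object, ...) {
  if (is.null(object$coefficients)) {
    abort("autoplot is only available for the final model form")
  }
  frame <- object$frame
  obs <- frame |>
    dplyr::group_by(hour = as.numeric(as.character(.data$hour_bin)) + 0.5,
                    sex = .data$sex) |>
    dplyr::summarise(rr = exp(stats::median(.data$log_rr)), .groups = "drop") |>
    dplyr::mutate(profile = ifelse(.data$sex == 1, "male", "female"))
  p <- plot_circadian_profile(
    object$coefficients,
    sex = sort(unique(frame$sex)),
    age = round(mean(frame$age), 1)
  )
  p +
    ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = .data$hour, y = .data$rr, colour = .data$profile)
    ) +
    ggplot2::labs(subtitle = "points: hourly medians of observed RR")
}
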