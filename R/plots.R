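# ggplot2 visualizations for the main result types

#' Plot empirical versus model jump-length CDFs
#'
#' One panel per lag time, empirical CDF as points and the fitted two-state
#' model as a line.
#'
#' @param object a `twostate_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.twostate_fit <- function(object, ...) {
  df <- object$cdf |>
    mutate(lag_label = sprintf("lag %d (%.0f ms)", .data$lag,
                               1000 * .data$time_s))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_um)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cdf), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "firebrick") +
    ggplot2::facet_wrap(~lag_label) +
    ggplot2::coord_cartesian(xlim = c(0, stats::quantile(object$cdf$r_um[
      object$cdf$cdf < 0.999], 1))) +
    ggplot2::labs(x = "jump length (µm)", y = "CDF",
                  title = sprintf("two-state fit: F_bound = %.2f",
                                  object$estimate$F_bound)) +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time survival curve with optional fit
#'
#' @param object a `survival_curve`.
#' @param fit optional `doubleexp_fit` overlaid as a line.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.survival_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$survival)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "1 - CDF") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    off <- fit$offset %||% 0
    tt <- seq(off, max(object$time_s), length.out = 200)
    pred <- tibble(time_s = tt,
                   survival = fit$f_sb * exp(-fit$k_sb * (tt - off)) +
                     fit$f_tb * exp(-fit$k_tb * (tt - off)))
    p <- p + ggplot2::geom_line(data = pred, colour = "firebrick")
  }
  p
}

#' Plot an occupancy time trace as an on/off bar
#'
#' Occupied intervals are drawn as filled bars on the upper row, vacant
#' intervals on the lower row, with vertical transition lines.
#'
#' @param object an `occupancy_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_trace <- function(object, ...) {
  df <- object |>
    mutate(ymin = ifelse(.data$state == "occupied", 0.55, 0),
           ymax = ifelse(.data$state == "occupied", 1, 0.45))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$state)) +
    ggplot2::scale_fill_manual(values = c(occupied = "steelblue",
                                          vacant = "grey80")) +
    ggplot2::scale_y_continuous(breaks = c(0.225, 0.775),
                                labels = c("vacant", "occupied")) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = unique(df$factor)[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Histogram of log10 diffusion coefficients with mixture overlay
#'
#' @param D_values numeric vector of diffusion coefficients, or a data
#'   frame with a `D` column.
#' @param mixture optional `gmm_fit` whose components are overlaid.
#' @param bins histogram bin count.
#' @return A ggplot object.
#' @export
plot_log10D_histogram <- function(D_values, mixture = NULL, bins = 40) {
  if (is.data.frame(D_values)) D_values <- D_values$D
  D_values <- D_values[is.finite(D_values) & D_values > 0]
  df <- tibble(log10D = log10(D_values))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log10D)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "white") +
    ggplot2::labs(x = expression(log[10] * D ~ "(µm²/s)"),
                  y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(mixture)) {
    grid <- seq(min(df$log10D), max(df$log10D), length.out = 300)
    dens <- purrr::pmap_dfr(mixture$components, function(component, mean, sd, weight) {
      tibble(component = component, log10D = grid,
             density = weight * stats::dnorm(grid, mean, sd))
    })
    p <- p + ggplot2::geom_line(
      data = dens,
      ggplot2::aes(y = .data$density, colour = .data$component))
  }
  p
}
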