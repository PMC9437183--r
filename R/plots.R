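#' Plot a tuning curve
#'
#' Mean rate against ITD (ms) or IPD (rad), with per-repetition rates shown
#' as translucent points.
#'
#' @param object A [tuning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tuning_curve <- function(object, ...) {
  ipd <- identical(attr(object, "axis_kind"), "ipd_rad")
  scale <- if (ipd) 1 else 1e3
  df <- as_tibble(object) |> mutate(axis = .data$axis_value * scale)
  m <- tidy(object) |> mutate(axis = .data$axis_value * scale)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis, y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(
      data = m, ggplot2::aes(y = .data$mean_rate),
      linewidth = 0.8, colour = "#2166ac"
    ) +
    ggplot2::labs(
      x = if (ipd) "IPD (rad)" else "ITD (ms)",
      y = "rate (sp/s)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tuning_curve
#' @param ensemble A [spike_ensemble()].
#' @param bin PSTH bin width (s).
#' @export
plot_psth <- function(ensemble, bin = 0.001) {
  df <- psth(ensemble, bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1e3, y = .data$count)) +
    ggplot2::geom_col(width = bin * 1e3, fill = "grey30") +
    ggplot2::labs(x = "time (ms)", y = "spikes per bin") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tuning_curve
#' @param frequency Reference frequency (Hz) for the period histogram.
#' @param n_bins Number of phase bins.
#' @export
plot_period_histogram <- function(ensemble, frequency, n_bins = 50) {
  df <- period_histogram(ensemble, frequency, n_bins)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$count)) +
    ggplot2::geom_col(width = 1 / n_bins, fill = "grey30") +
    ggplot2::labs(x = "phase (cycles)", y = "spikes per bin") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tuning_curve
#' @param stimulus An [acoustic_stimulus()] or [electric_pulse_train()].
#' @param t_max Plot only the first `t_max` seconds.
#' @export
plot_stimulus <- function(stimulus, t_max = 0.05) {
  if (inherits(stimulus, "acoustic_stimulus")) {
    df <- tidy(stimulus) |> filter(.data$time <= t_max)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1e3, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (ms)", y = "pressure (Pa)") +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(stimulus) |> filter(.data$pulse_time <= t_max)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$pulse_time * 1e3, xend = .data$pulse_time * 1e3,
      y = 0, yend = .data$amplitude
    )) +
      ggplot2::geom_segment(linewidth = 0.4) +
      ggplot2::labs(x = "time (ms)", y = "current (uA)") +
      ggplot2::theme_minimal()
  }
}
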