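#' Plot an averaged ERG trace with its measured waves
#'
#' Shows the filtered, averaged flash response of one flash strength with
#' the flash onset, the measured a-trough and the b-peak marked.
#'
#' @param recording An [erg_recording()].
#' @param luminance Flash strength to plot.
#' @param config An [erg_config()].
#' @param filter Band-pass filter the average before plotting/measuring.
#' @return A ggplot object.
#' @export
plot_erg_trace <- function(recording, luminance, config = erg_config(),
                           filter = TRUE) {
  trace <- average_sweeps(recording, luminance)
  if (filter)
    trace <- bandpass_filter(trace, recording$sampling_rate,
                             config$filter_low, config$filter_high)
  res <- measure_waves(trace, recording$stimulus_onset,
                       recording$sampling_rate, config, luminance)
  df <- tibble(time_ms = recording_time_ms(recording), uV = trace)
  marks <- tibble(
    wave = c("a", "b"),
    time_ms = c(res$a_implicit, res$b_implicit)
  ) |>
    filter(!is.na(.data$time_ms)) |>
    left_join(df, by = "time_ms")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(data = marks, colour = "red", size = 2) +
    ggplot2::labs(x = "Time from flash (ms)", y = "Amplitude (uV)",
                  title = sprintf("%s, %g cd.s/m2", recording$eye_id, luminance),
                  subtitle = sprintf("a = %.0f uV, b = %.0f uV",
                                     res$a_amplitude, res$b_amplitude)) +
    ggplot2::theme_minimal()
}

#' Intensity-response plot of measured ERG amplitudes
#' @param object An `erg_wave_results` tibble from [analyze_recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erg_wave_results
#' @export
autoplot.erg_wave_results <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(c("a_amplitude", "b_amplitude"),
                        names_to = "wave", values_to = "amplitude") |>
    mutate(wave = sub("_amplitude", "", .data$wave))
  ggplot2::ggplot(df, ggplot2::aes(.data$luminance, .data$amplitude,
                                   colour = .data$wave)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Flash strength (cd.s/m2)", y = "Amplitude (uV)",
                  colour = "Wave",
                  title = "ERG intensity-response series") +
    ggplot2::theme_minimal()
}

#' Raster plot of an en-face thickness map
#' @param object A [thickness_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thickness_map
#' @export
autoplot.thickness_map <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$valid)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$thickness_um)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "um") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = paste(object$layer, "thickness map")) +
    ggplot2::theme_minimal()
}

#' Bar plot of quadrant/ring sector means
#' @param object A [sector_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sector_summary
#' @export
autoplot.sector_summary <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(c("inner_mean", "outer_mean", "combined"),
                        names_to = "ring", values_to = "thickness_um")
  ggplot2::ggplot(df, ggplot2::aes(.data$quadrant, .data$thickness_um,
                                   fill = .data$ring)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Thickness (um)",
                  title = paste("Sector summary,", object$layer[1])) +
    ggplot2::theme_minimal()
}
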