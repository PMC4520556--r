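#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the package's result types: a perfusion trace
#' (DC/Vel/Vol versus time, QC failures marked), a frame spectrum (power
#' versus frequency with the noise floor), a linearity experiment (mean Vel
#' and Vol versus speed with the fitted line) and a protocol run (per-rat
#' segment means).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name ldfsim-plots
NULL

#' @rdname ldfsim-plots
#' @export
autoplot.ldf_trace <- function(object, ...) {
  long <- object |>
    dplyr::select("time", "dc", "vel", "vol", "quality_ok") |>
    tidyr::pivot_longer(c("dc", "vel", "vol"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = c("dc", "vel", "vol"),
                                     labels = c("DC (V)", "Vel (Hz)",
                                                "Vol (a.u.)")))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::filter(long, !.data$quality_ok),
                        colour = "red", size = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$parameter),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Perfusion trace (QC failures in red)")
}

#' @rdname ldfsim-plots
#' @export
autoplot.ldf_spectrum <- function(object, ...) {
  df <- tibble::tibble(frequency = object$frequency, power = object$power)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$noise_floor, linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Doppler shift (Hz)", y = expression(PSD~(V^2/Hz)),
                  title = "Frame power spectrum (dashed: noise floor)")
}

#' @rdname ldfsim-plots
#' @export
autoplot.ldf_linearity <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(.data$speed, .data$vel_mean)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$vel_mean - .data$vel_sd,
      ymax = .data$vel_mean + .data$vel_sd)) +
    ggplot2::labs(
      x = "speed (mm/s)", y = "mean Vel (Hz)",
      title = sprintf("%s linearity: r = %.4f", object$scene_kind,
                      object$pearson_r)
    )
}

#' @rdname ldfsim-plots
#' @export
autoplot.ldf_protocol <- function(object, ...) {
  df <- object$segment_means |>
    dplyr::mutate(segment = factor(.data$segment,
                                   levels = unique(.data$segment)))
  ggplot2::ggplot(df, ggplot2::aes(.data$segment, .data$vel_mean,
                                   group = .data$rat)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "segment mean Vel (Hz)",
      title = sprintf("%s (%s): mean decrease %.1f%%", object$protocol,
                      object$site, object$mean_change)
    )
}
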