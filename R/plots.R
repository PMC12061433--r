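#' Raster plot of a recording
#'
#' @param object A `tc_recording`.
#' @param populations Populations to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tc_recording <- function(object, populations = c("exc", "thal"),
                                  ...) {
  d <- object$spikes[object$spikes$population %in% populations, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms / 1000, y = .data$cell)) +
    ggplot2::geom_point(size = 0.1, shape = ".") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$population),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "time (s)", y = "cell") +
    ggplot2::theme_minimal()
}

#' Psychometric curve with its fit
#'
#' @param object A `psychfit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psychfit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$intensity,
                                       y = .data$p_response)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus intensity (pA)", y = "response probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (object$converged) {
    xx <- seq(min(d$intensity), max(d$intensity), length.out = 200)
    curve_d <- tibble::tibble(
      intensity = xx,
      p_response = psychometric_fun(xx, object$par$alpha, object$par$beta,
                                    object$par$lambda, object$par$gamma))
    p <- p + ggplot2::geom_line(data = curve_d)
  }
  p
}

#' Dominance-duration histogram with the Gamma fit
#'
#' @param stats A `dominance_stats` with fits.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_dominance_durations <- function(stats, bins = 20) {
  d <- tibble::tibble(duration_s = stats$durations_s)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$duration_s)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::labs(x = "dominance duration (s)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(stats$gamma_shape)) {
    xx <- seq(0.01, max(d$duration_s), length.out = 200)
    fit_d <- tibble::tibble(
      duration_s = xx,
      density = stats::dgamma(xx, shape = stats$gamma_shape,
                              scale = stats$gamma_scale))
    p <- p + ggplot2::geom_line(data = fit_d,
                                ggplot2::aes(y = .data$density))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
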