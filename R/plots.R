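#' Plot a trace with detected events
#'
#' @param trace A trace tibble.
#' @param events Optional event tibble; peaks are marked.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, events = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time, .data$current)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events))
    p <- p + ggplot2::geom_point(
      data = events,
      ggplot2::aes(.data$t_peak, .data$amplitude),
      colour = "red", shape = 25, size = 1.5)
  p
}

#' @describeIn parabola_fit Plot the binned variance-mean relation and the
#'   fitted parabola.
#' @param object An `nsfa_result`.
#' @param ... Unused.
#' @method autoplot nsfa_result
#' @export
autoplot.nsfa_result <- function(object, ...) {
  b <- object$binned
  grid <- tibble::tibble(
    mean_current = seq(0, min(b$mean_current), length.out = 200))
  grid$variance <- object$i * grid$mean_current -
    grid$mean_current^2 / object$n_channels + object$var_baseline
  ggplot2::ggplot(b, ggplot2::aes(.data$mean_current, .data$variance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "mean current (pA)", y = expression(sigma^2 ~ (pA^2)),
                  subtitle = sprintf("i = %.2f pA, N = %.1f",
                                     object$i, object$n_channels)) +
    ggplot2::theme_minimal()
}

#' @describeIn pp_recovery Plot the recovery curve and its exponential fit.
#' @param object A `recovery_curve`.
#' @param ... Unused.
#' @method autoplot recovery_curve
#' @export
autoplot.recovery_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(.data$interval, .data$ratio)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::ylim(0, NA) +
    ggplot2::labs(x = "inter-pulse interval (s)",
                  y = "paired-pulse ratio") +
    ggplot2::theme_minimal()
  if (is.finite(object$d)) {
    grid <- tibble::tibble(
      interval = seq(min(object$curve$interval),
                     max(object$curve$interval), length.out = 200))
    grid$ratio <- 1 - object$d * exp(-grid$interval / object$tau_rec_s)
    p <- p + ggplot2::geom_line(data = grid, colour = "red")
  }
  p
}

#' @describeIn fit_skewt_mixture Scatter the first two feature dimensions
#'   coloured by hard cluster label (supply the fitted data).
#' @param object A `mixture_fit`.
#' @param data The feature matrix the mixture was fitted to.
#' @param dims Two column indices to plot.
#' @param ... Unused.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, data, dims = c(1, 2), ...) {
  df <- tibble::tibble(x = data[, dims[1]], y = data[, dims[2]],
                       cluster = factor(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::labs(x = paste("feature", dims[1]),
                  y = paste("feature", dims[2])) +
    ggplot2::theme_minimal()
}
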