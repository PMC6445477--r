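#' Plot a linear filter's impulse response
#'
#' @param object a `linear_filter`.
#' @param t_max,n plotting grid.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.linear_filter <- function(object, t_max = NULL, n = 400, ...) {
  if (is.null(t_max)) t_max <- 6 * max(-1 / Re(object$lambda))
  t <- seq(0, t_max, length.out = n)
  df <- tibble(t = t, h = filter_evaluate(object, t))
  ggplot2::ggplot(df, ggplot2::aes(t, .data$h)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time", y = "h(t)", title = "Impulse response")
}

#' Plot a heterogeneous stability boundary with the eigenvalue disk
#'
#' @param object a `stability_report`.
#' @param radius optional disk radius `J_cs` to overlay.
#' @param ... unused.
#' @return a ggplot in the connectivity-eigenvalue plane.
#' @export
autoplot.stability_report <- function(object, radius = NULL, ...) {
  b <- object$boundary
  curve <- tibble(re = c(rev(b$re), b$re), im = c(-rev(b$im), b$im))
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$re, .data$im)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re lambda_J", y = "Im lambda_J",
                  title = sprintf("Stability boundary (R* = %.3f, %s)",
                                  object$critical_radius, object$bifurcation))
  if (!is.null(radius)) {
    th <- seq(0, 2 * pi, length.out = 200)
    p <- p + ggplot2::geom_path(
      data = tibble(re = radius * cos(th), im = radius * sin(th)),
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a full-Jacobian eigenvalue spectrum
#'
#' @param object a `jacobian_spectrum`.
#' @param ... unused.
#' @return a ggplot of the 2N eigenvalues with the stability line.
#' @export
autoplot.jacobian_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$re, .data$im)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "Re lambda", y = "Im lambda",
                  title = sprintf("Network eigenvalues (%d unstable)",
                                  object$n_unstable))
}

#' Plot sample unit rates and the population average of a trajectory
#'
#' @param object a `trajectory`.
#' @param n_units number of individual units to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trajectory <- function(object, n_units = 8, ...) {
  df <- tidy(object, n_units = n_units)
  pa <- population_average(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$rate,
                                   group = .data$unit)) +
    ggplot2::geom_line(alpha = 0.45, linewidth = 0.3,
                       ggplot2::aes(colour = factor(.data$unit))) +
    ggplot2::geom_line(data = pa, ggplot2::aes(group = NULL, colour = NULL),
                       colour = "black", linewidth = 0.8) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "time", y = "rate")
}

#' Plot an autocorrelation estimate
#'
#' @param object an `autocorr_estimate` or `dmft_state`.
#' @param envelope overlay the analytic-signal envelope.
#' @param ... unused.
#' @return a ggplot of `C(tau)`.
#' @export
autoplot.autocorr_estimate <- function(object, envelope = TRUE, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag", y = "C(tau)")
  if (envelope) {
    ts <- envelope_timescale(object)
    if (!ts$failed) {
      base <- mean(tail(df$C, max(2, round(0.1 * nrow(df)))))
      env <- ts$envelope
      env$envelope <- env$envelope + base
      p <- p + ggplot2::geom_line(data = env,
                                  ggplot2::aes(.data$lag, .data$envelope),
                                  linetype = "dashed", colour = "red")
    }
  }
  p
}

#' @export
autoplot.dmft_state <- function(object, envelope = TRUE, ...) {
  autoplot.autocorr_estimate(object$estimate, envelope = envelope, ...)
}
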