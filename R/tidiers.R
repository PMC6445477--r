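#' Tidy a linear filter into its modes
#'
#' @param x a `linear_filter`.
#' @param ... unused.
#' @return a tibble with one row per mode: amplitude (re/im), rate (re/im),
#'   power, decay timescale.
#' @export
tidy.linear_filter <- function(x, ...) {
  tibble(a_re = Re(x$a), a_im = Im(x$a),
         lambda_re = Re(x$lambda), lambda_im = Im(x$lambda),
         power = x$power, tau = -1 / Re(x$lambda))
}

#' @export
glance.linear_filter <- function(x, ...) {
  tibble(n_modes = length(x$a), area = filter_area(x),
         tau_corr = filter_timescale(x)$tau_corr,
         variance_gain = white_noise_variance_gain(x),
         stable = filter_is_stable(x))
}

#' @export
tidy.spectrum_summary <- function(x, ...) {
  tibble(re = Re(x$eigenvalues), im = Im(x$eigenvalues),
         modulus = Mod(x$eigenvalues))
}

#' @export
glance.spectrum_summary <- function(x, ...) {
  tibble(N = x$N, radius_theory = x$radius_theory,
         outlier_theory = x$outlier_theory,
         radius_observed = sort(Mod(x$eigenvalues), decreasing = TRUE)[2],
         outlier_observed =
           Re(x$eigenvalues[which.min(Mod(x$eigenvalues - x$outlier_theory))]))
}

#' @export
tidy.fixed_points <- function(x, ...) x$solutions

#' @export
glance.popavg_report <- function(x, ...) {
  tibble(mechanism = x$params$mechanism, J_eff = x$J_eff,
         classification = x$classification, trace = x$trace,
         determinant = x$determinant,
         lambda_plus_re = Re(x$eigen$values[1]),
         lambda_minus_re = Re(x$eigen$values[2]),
         active_boundary = attr(x$critical_couplings, "active"),
         critical_coupling = min(x$critical_couplings))
}

#' @export
tidy.stability_report <- function(x, ...) x$boundary

#' @export
glance.stability_report <- function(x, ...) {
  tibble(mechanism = x$params$mechanism,
         critical_radius = x$critical_radius,
         critical_frequency = x$critical_frequency,
         bifurcation = x$bifurcation)
}

#' @export
tidy.jacobian_spectrum <- function(x, ...) {
  tibble(re = Re(x$values), im = Im(x$values))
}

#' @export
glance.jacobian_spectrum <- function(x, ...) {
  tibble(n_modes = length(x$values), n_unstable = x$n_unstable,
         max_mapping_error = x$max_mapping_error, radius = x$radius)
}

#' @export
tidy.autocorr_estimate <- function(x, ...) {
  tibble(lag = x$lags, C = x$C, Delta = x$Delta)
}

#' @export
glance.autocorr_estimate <- function(x, ...) {
  tibble(mu = x$mu, mean_rate = x$mean_rate, Delta0 = x$Delta[1],
         C0 = x$C[1], rate_variance = x$C[1] - x$mean_rate^2)
}

#' @export
tidy.dmft_state <- function(x, ...) tidy(x$estimate)

#' @export
glance.dmft_state <- function(x, ...) {
  tibble(mechanism = x$params$mechanism, J_eff = x$J_eff, J_cs = x$J_cs,
         sigma_eta = x$sigma_eta, converged = x$converged,
         iterations = x$iterations, mu = x$estimate$mu,
         mean_rate = x$estimate$mean_rate, Delta0 = x$estimate$Delta[1])
}

#' @export
tidy.timescale_result <- function(x, ...) {
  if (is.null(x$envelope)) return(tibble(lag = numeric(), envelope = numeric()))
  x$envelope
}

#' @export
glance.timescale_result <- function(x, ...) {
  tibble(tau_corr = x$tau_corr, method = x$method, failed = isTRUE(x$failed))
}

#' @export
tidy.trajectory <- function(x, n_units = 10, ...) {
  keep <- seq_len(min(n_units, nrow(x$x)))
  rates <- unit_rates(x)
  purrr::map_dfr(keep, function(i) {
    tibble(unit = i, time = x$times, rate = rates[i, ])
  })
}
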