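#' Rate autocorrelation of a simulated trajectory
#'
#' Per-unit time-averaged raw second moment of the firing rate,
#' `C(tau) = <phi_i(t) phi_i(t + tau)>`, averaged over units, together with
#' the current autocovariance `Delta(tau)` (population-and-time mean
#' subtracted). Lags use the stored sampling interval.
#'
#' @param traj a `trajectory`.
#' @param max_lag largest lag (default a quarter of the usable window).
#' @param burn_in initial time discarded before averaging.
#' @return an `autocorr_estimate` (see [single_unit_stochastic_sim()]).
#' @export
rate_autocorrelation <- function(traj, max_lag = NULL, burn_in = 0) {
  keep <- traj$times >= burn_in
  dts <- traj$dt * traj$store_every
  nt <- sum(keep)
  if (is.null(max_lag)) max_lag <- (nt - 1) * dts / 4
  lag_steps <- round(max_lag / dts)
  if (nt < lag_steps * 4)
    abort("trajectory too short for the requested burn-in and max_lag")
  X <- t(traj$x[, keep, drop = FALSE])        # time x units
  PHI <- transfer(X, traj$params$gamma, traj$params$phi_max)
  mu <- mean(X)
  C <- cross_moment_fft(PHI, lag_steps)
  Delta <- cross_moment_fft(X - mu, lag_steps)
  structure(list(lags = (0:lag_steps) * dts, Delta = Delta, C = C,
                 mu = mu, mean_rate = mean(PHI), dt = dts,
                 trials = ncol(X)),
            class = "autocorr_estimate")
}

# analytic signal of a real series via one-sided FFT weighting
analytic_signal <- function(x) {
  m <- length(x)
  X <- fft(x)
  h <- numeric(m)
  h[1] <- 1
  if (m %% 2 == 0) {
    h[m / 2 + 1] <- 1
    h[2:(m / 2)] <- 2
  } else h[2:((m + 1) / 2)] <- 2
  fft(X * h, inverse = TRUE) / m
}

#' Envelope-based timescale of an autocorrelation function
#'
#' Estimates the characteristic decay time of a (possibly oscillatory)
#' autocorrelation as twice the lag at which its envelope first reaches
#' `exp(-1/2)` of the lag-0 value, with linear interpolation between grid
#' points. The envelope is obtained from the analytic signal (Hilbert
#' transform of the evenly extended, baseline-removed autocorrelation) by
#' coherent demodulation at the dominant spectral frequency `w0`:
#' `E(tau) = Re(z(tau) exp(-i w0 tau))`. For a monotone autocorrelation
#' `w0 = 0` and the envelope is the function itself, so an exponential
#' `exp(-tau/tau0)` yields `tau_corr = tau0` and a Gaussian
#' `exp(-tau^2/(2 sigma^2))` yields `2 sigma`; for a damped oscillation the
#' demodulated envelope tracks the amplitude across the zero crossings. The
#' baseline (plateau) is estimated as the mean of the last 10% of lags and
#' subtracted first.
#'
#' @param C an `autocorr_estimate` (its `C` component is used) or a numeric
#'   autocorrelation vector.
#' @param lags lag grid (required when `C` is a bare vector).
#' @return an object of class `timescale_result`: `tau_corr` (`NA` with
#'   `failed = TRUE` when the envelope never reaches the threshold within the
#'   grid), `method = "envelope"`, the sampled `envelope` tibble and the
#'   demodulation frequency `omega0`.
#' @examples
#' lags <- seq(0, 10, 0.01)
#' envelope_timescale(exp(-lags), lags)$tau_corr  # ~ 1
#' @export
envelope_timescale <- function(C, lags = NULL) {
  if (inherits(C, "autocorr_estimate")) {
    lags <- C$lags
    C <- C$C
  }
  stopifnot(length(C) == length(lags), length(C) >= 8)
  n <- length(C)
  base <- mean(tail(C, max(2, round(0.1 * n))))
  C0 <- C - base
  x <- c(C0, rev(C0[2:(n - 1)]))  # even circular extension
  m <- length(x)
  X <- fft(x)
  half <- floor(m / 2)
  kpk <- which.max(Mod(X[1:(half + 1)])^2) - 1
  dlag <- lags[2] - lags[1]
  w0 <- 2 * pi * kpk / (m * dlag)
  z <- analytic_signal(x)[1:n]
  env <- Re(z * exp(-1i * w0 * lags))
  thr <- env[1] * exp(-0.5)
  below <- which(env <= thr)
  below <- below[below > 1]
  if (length(below) == 0 || env[1] <= 0) {
    return(structure(list(tau_corr = NA_real_, method = "envelope",
                          envelope = tibble(lag = lags, envelope = env),
                          omega0 = w0, failed = TRUE),
                     class = "timescale_result"))
  }
  k <- below[1]
  t0 <- lags[k - 1] + dlag * (env[k - 1] - thr) / (env[k - 1] - env[k])
  structure(list(tau_corr = 2 * t0, method = "envelope",
                 envelope = tibble(lag = lags, envelope = env),
                 omega0 = w0, failed = FALSE),
            class = "timescale_result")
}
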