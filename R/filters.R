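#' Sum-of-exponential-modes linear filter
#'
#' Represents a causal impulse response
#' \eqn{h(t) = \sum_k a_k t^{p_k} e^{\lambda_k t}} for `t >= 0` (0 for
#' `t < 0`). Complex modes come in conjugate pairs so `h` is real; a power
#' `p_k = 1` marks the polynomial term of a degenerate (equal-rate) filter,
#' kept exact rather than obtained by perturbing rates.
#'
#' @param a complex vector of mode amplitudes.
#' @param lambda complex vector of mode rates (negative real part if stable).
#' @param power integer vector of polynomial powers (0 or 1).
#' @param mechanism optional label.
#' @return an object of class `linear_filter`.
#' @export
linear_filter <- function(a, lambda, power = rep(0L, length(a)),
                          mechanism = NA_character_) {
  stopifnot(length(a) == length(lambda), length(power) == length(a))
  structure(list(a = as.complex(a), lambda = as.complex(lambda),
                 power = as.integer(power), mechanism = mechanism),
            class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  cat("<linear_filter>", if (!is.na(x$mechanism)) x$mechanism else "", "\n")
  for (k in seq_along(x$a))
    cat(sprintf("  mode %d: a = %s, lambda = %s, power = %d\n", k,
                format(x$a[k], digits = 4), format(x$lambda[k], digits = 4),
                x$power[k]))
  invisible(x)
}

filter_is_stable <- function(h) all(Re(h$lambda) < 0)

#' Evaluate a linear filter on a time grid
#'
#' @param h a [linear_filter()].
#' @param t numeric vector of times; `h(t) = 0` for `t < 0`.
#' @return numeric vector `h(t)`.
#' @export
filter_evaluate <- function(h, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  acc <- rep(0 + 0i, length(tp))
  for (k in seq_along(h$a))
    acc <- acc + h$a[k] * tp^h$power[k] * exp(h$lambda[k] * tp)
  out[pos] <- Re(acc)
  out
}

#' Total area under a linear filter
#'
#' \eqn{\int_0^\infty h = \sum_k a_k\, p_k! / (-\lambda_k)^{p_k+1}} (the DC
#' gain of the filter).
#'
#' @param h a stable [linear_filter()].
#' @return the integral of `h` over `[0, Inf)`.
#' @export
filter_area <- function(h) {
  if (!filter_is_stable(h)) abort("filter has unstable modes; area diverges")
  Re(sum(h$a * factorial(h$power) / (-h$lambda)^(h$power + 1)))
}

#' Synaptic-filtering impulse response
#'
#' The current response of a single unit with synaptic filtering to an input
#' pulse: two exponentials with time constants `tau_s` and `tau_m`, opposite
#' signs and equal amplitude `1/(tau_s - tau_m)`, total area 1. The degenerate
#' case `tau_s = tau_m` is the exact limit `t exp(-t/tau_m)/tau_m^2`,
#' represented with a polynomial mode.
#'
#' @param tau_m membrane time constant.
#' @param tau_s synaptic time constant.
#' @return a `linear_filter`.
#' @examples
#' filter_area(synaptic_filter(1, 5))  # 1
#' @export
synaptic_filter <- function(tau_m, tau_s) {
  stopifnot(tau_m > 0, tau_s > 0)
  if (abs(tau_s - tau_m) < 1e-9 * tau_m) {
    return(linear_filter(a = 1 / tau_m^2, lambda = -1 / tau_m, power = 1L,
                         mechanism = "synaptic"))
  }
  linear_filter(a = c(1, -1) / (tau_s - tau_m),
                lambda = c(-1 / tau_s, -1 / tau_m),
                mechanism = "synaptic")
}

# eigenvalues/vectors of a real 2x2 matrix as exact (possibly complex) pairs
eigen_pair_2x2 <- function(A) {
  tr <- A[1, 1] + A[2, 2]
  dt <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- as.complex(tr^2 - 4 * dt)
  sq <- sqrt(disc)
  lam <- c((tr + sq) / 2, (tr - sq) / 2)
  vecs <- vapply(lam, function(l) {
    # rows of (A - l I) are proportional; use the larger one
    r1 <- c(A[1, 1] - l, A[1, 2])
    r2 <- c(A[2, 1], A[2, 2] - l)
    v <- if (Mod(r1[1]) + Mod(r1[2]) >= Mod(r2[1]) + Mod(r2[2]))
      c(-r1[2], r1[1]) else c(-r2[2], r2[1])
    v / sqrt(sum(Mod(v)^2))
  }, complex(2))
  structure(list(values = lam, vectors = vecs, matrix = A),
            class = "eigen_pair")
}

#' @export
print.eigen_pair <- function(x, ...) {
  cat("<eigen_pair> lambda+ =", format(x$values[1], digits = 6),
      " lambda- =", format(x$values[2], digits = 6), "\n")
  invisible(x)
}

#' Dynamic matrix and eigensystem of a single adaptive unit
#'
#' The 2D system coupling the current `x` and the adaptation variable `w` has
#' dynamic matrix `A = [[-1/tau_m, -g_w/tau_m], [1/tau_w, -1/tau_w]]`. Its
#' eigenvalues are complex iff `g_w > (tau_w - tau_m)^2 / (4 tau_m tau_w)`, in
#' which case their common real part is `-(tau_m + tau_w)/(2 tau_m tau_w)`.
#'
#' @param tau_m membrane time constant.
#' @param tau_w adaptation time constant.
#' @param g_w adaptation coupling.
#' @return an `eigen_pair` object: `values` (lambda+ first), unit-norm
#'   `vectors` (columns), and the `matrix` itself.
#' @export
adaptive_eigensystem <- function(tau_m, tau_w, g_w) {
  stopifnot(tau_m > 0, tau_w > 0, g_w >= 0)
  A <- matrix(c(-1 / tau_m, 1 / tau_w, -g_w / tau_m, -1 / tau_w), 2, 2)
  eigen_pair_2x2(A)
}

# impulse response of a 2x2 system: entry [row, col] of exp(A t) scaled by
# `gain` (how the input enters the driven equation)
propagator_filter <- function(A, row, col, gain, mechanism = NA_character_) {
  ep <- eigen_pair_2x2(A)
  lp <- ep$values[1]
  lm <- ep$values[2]
  sel <- function(M) M[row, col]
  I2 <- diag(2)
  if (Mod(lp - lm) < 1e-11 * max(Mod(lp), 1)) {
    # defective/degenerate: exp(At) = e^{lt} (I + (A - l I) t)
    return(linear_filter(a = gain * c(sel(I2), sel(A - Re(lp) * I2)),
                         lambda = rep(Re(lp), 2), power = c(0L, 1L),
                         mechanism = mechanism))
  }
  # exp(At) = [ (A - lm I) e^{lp t} - (A - lp I) e^{lm t} ] / (lp - lm)
  ap <- gain * sel(A - lm * I2) / (lp - lm)
  am <- -gain * sel(A - lp * I2) / (lp - lm)
  linear_filter(a = c(ap, am), lambda = c(lp, lm), mechanism = mechanism)
}

#' Adaptive-unit impulse response
#'
#' Exact current response of a single adaptive unit to an input pulse,
#' computed from the propagator of its 2D dynamic matrix. The input enters the
#' current equation directly, so `h(0+) = 1/tau_m`. For slow adaptation the
#' slow mode has rate `-(1+g_w)/tau_w` and area tending to `-g_w/(1+g_w)`,
#' independent of `tau_w`.
#'
#' @inheritParams adaptive_eigensystem
#' @return a `linear_filter`.
#' @export
adaptive_filter <- function(tau_m, tau_w, g_w) {
  stopifnot(tau_m > 0, tau_w > 0, g_w >= 0)
  A <- matrix(c(-1 / tau_m, 1 / tau_w, -g_w / tau_m, -1 / tau_w), 2, 2)
  propagator_filter(A, 1, 1, gain = 1 / tau_m, mechanism = "adaptation")
}

#' Convolve a linear filter with an input time series
#'
#' Discrete causal convolution `x[n] = dt * sum_k h[k] I[n-k]` on a uniform
#' grid. A delta input (`1/dt` at `t = 0`) returns the filter samples up to
#' `O(dt)`.
#'
#' @param h a [linear_filter()].
#' @param input numeric input series sampled at `dt`.
#' @param dt sampling interval.
#' @return numeric response series, same length as `input`.
#' @export
filter_response <- function(h, input, dt) {
  n <- length(input)
  hh <- filter_evaluate(h, (seq_len(n) - 1) * dt)
  m <- stats::nextn(2 * n, 2)
  X <- fft(c(hh, numeric(m - n))) * fft(c(input, numeric(m - n)))
  dt * Re(fft(X, inverse = TRUE) / m)[seq_len(n)]
}

#' Amplitude-weighted timescale of a linear filter
#'
#' \eqn{\tau_{corr} = \sum_k |a_k| \tau_k / \sum_k |a_k|} with
#' \eqn{\tau_k = -1/\mathrm{Re}\,\lambda_k}; a complex-conjugate pair shares
#' one decay timescale (and, having equal `|a|` and equal `tau`, enters the
#' weighted mean exactly as a single mode).
#'
#' @param h a stable [linear_filter()].
#' @return an object of class `timescale_result` with `tau_corr` and
#'   `method = "weighted_modes"`.
#' @examples
#' filter_timescale(synaptic_filter(1, 5))$tau_corr  # (1 + 5) / 2
#' @export
filter_timescale <- function(h) {
  if (!filter_is_stable(h))
    abort("timescale undefined for an unstable filter")
  w <- Mod(h$a)
  tau <- -1 / Re(h$lambda)
  structure(list(tau_corr = sum(w * tau) / sum(w), method = "weighted_modes",
                 envelope = NULL, failed = FALSE),
            class = "timescale_result")
}

#' @export
print.timescale_result <- function(x, ...) {
  cat("<timescale_result>", x$method, ": tau_corr =",
      format(x$tau_corr, digits = 6), "\n")
  if (isTRUE(x$failed)) cat("  (envelope never crossed threshold)\n")
  invisible(x)
}

#' Output variance of a filter driven by unit-spectral-density white noise
#'
#' Returns \eqn{\int_0^\infty h(t)^2\,dt}, the stationary output variance when
#' the input is Gaussian white noise normalised to unit spectral density,
#' \eqn{\langle I(t) I(t')\rangle = \delta(t - t')} (the only normalisation
#' under which this gain is finite). Closed form from the modes:
#' \eqn{\sum_{jk} a_j a_k (p_j + p_k)! / (-(\lambda_j+\lambda_k))^{p_j+p_k+1}}.
#'
#' @param h a stable [linear_filter()].
#' @return the variance gain (dimensionless x 1/time).
#' @examples
#' white_noise_variance_gain(synaptic_filter(1, 1))  # 1/(2*(1+1)) = 0.25
#' @export
white_noise_variance_gain <- function(h) {
  if (!filter_is_stable(h))
    abort("variance gain undefined for an unstable filter")
  acc <- 0 + 0i
  for (j in seq_along(h$a)) for (k in seq_along(h$a)) {
    p <- h$power[j] + h$power[k]
    lam <- h$lambda[j] + h$lambda[k]
    acc <- acc + h$a[j] * h$a[k] * factorial(p) / (-lam)^(p + 1)
  }
  Re(acc)
}
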