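#' Threshold-linear transfer function with saturation
#'
#' Maps an input current to an instantaneous firing rate,
#' \eqn{\phi(x) = \min([x - \gamma]^+, \phi_{max})}: zero below the activation
#' threshold \eqn{\gamma}, linear with unit slope above it, saturating at
#' \eqn{\phi_{max}}.
#'
#' @param x numeric vector of input currents.
#' @param gamma activation threshold (current units), or a [unit_params()]
#'   object from which `gamma` and `phi_max` are taken.
#' @param phi_max maximum firing rate (must be positive).
#' @return numeric vector of rates in `[0, phi_max]`.
#' @examples
#' transfer(0)            # 0.5 with the default gamma = -0.5
#' transfer(c(-1, 0, 10)) # clamped at both ends
#' @export
transfer <- function(x, gamma = -0.5, phi_max = 2) {
  if (inherits(gamma, "unit_params")) {
    phi_max <- gamma$phi_max
    gamma <- gamma$gamma
  }
  stopifnot(phi_max > 0)
  pmin(pmax(x - gamma, 0), phi_max)
}

#' Derivative of the transfer function
#'
#' Equals 1 strictly inside the linear region \eqn{\gamma < x < \gamma +
#' \phi_{max}} and 0 outside. The derivative at the two kink points is defined
#' as 0: linearisations are only ever taken at fixed points strictly inside a
#' region.
#'
#' @inheritParams transfer
#' @return numeric vector of 0/1 values.
#' @export
transfer_derivative <- function(x, gamma = -0.5, phi_max = 2) {
  if (inherits(gamma, "unit_params")) {
    phi_max <- gamma$phi_max
    gamma <- gamma$gamma
  }
  stopifnot(phi_max > 0)
  as.numeric(x > gamma & x < gamma + phi_max)
}

#' Single-unit parameters
#'
#' Bundles the constants describing one rate unit: the membrane time constant
#' `tau_m` (the unit of time throughout), the slow mechanism (`"adaptation"`,
#' a hidden variable low-pass filtering the linearised rate and fed back
#' negatively with coupling `g_w` and time constant `tau_w`; or `"synaptic"`,
#' a feed-forward low-pass filter of the summed input with time constant
#' `tau_s`), and the transfer-function constants `gamma` and `phi_max`.
#'
#' @param mechanism `"adaptation"` or `"synaptic"`.
#' @param tau_m membrane time constant (> 0).
#' @param g_w adaptation coupling (>= 0, adaptation only).
#' @param tau_w adaptation time constant (> 0, adaptation only).
#' @param tau_s synaptic time constant (> 0, synaptic only).
#' @param gamma activation threshold.
#' @param phi_max maximum firing rate (> 0).
#' @return an object of class `unit_params`.
#' @examples
#' unit_params("adaptation", g_w = 0.5, tau_w = 5)
#' unit_params("synaptic", tau_s = 5)
#' @export
unit_params <- function(mechanism = c("adaptation", "synaptic"), tau_m = 1,
                        g_w = NULL, tau_w = NULL, tau_s = NULL,
                        gamma = -0.5, phi_max = 2) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(tau_m), tau_m > 0, phi_max > 0)
  if (mechanism == "adaptation") {
    if (is.null(g_w) || is.null(tau_w))
      abort("adaptation units need `g_w` and `tau_w`")
    stopifnot(g_w >= 0, tau_w > 0)
    tau_s <- NULL
  } else {
    if (is.null(tau_s)) abort("synaptic units need `tau_s`")
    stopifnot(tau_s > 0)
    g_w <- NULL
    tau_w <- NULL
  }
  structure(list(mechanism = mechanism, tau_m = tau_m, g_w = g_w,
                 tau_w = tau_w, tau_s = tau_s,
                 gamma = gamma, phi_max = phi_max),
            class = "unit_params")
}

#' @export
print.unit_params <- function(x, ...) {
  cat("<unit_params> mechanism:", x$mechanism, "\n")
  cat("  tau_m =", x$tau_m)
  if (x$mechanism == "adaptation")
    cat(", g_w =", x$g_w, ", tau_w =", x$tau_w)
  else cat(", tau_s =", x$tau_s)
  cat("\n  transfer: gamma =", x$gamma, ", phi_max =", x$phi_max, "\n")
  invisible(x)
}

# time constant of the hidden (slow) variable
tau_hidden <- function(params) {
  if (params$mechanism == "adaptation") params$tau_w else params$tau_s
}

mech_code <- function(params) if (params$mechanism == "adaptation") 0L else 1L

#' Intrinsic-noise parameters
#'
#' White-noise input intensity for every unit, with the convention
#' \eqn{\langle\eta(t)\eta(t')\rangle = (\sigma_\eta^2/2)\,\delta(t-t')}.
#'
#' @param sigma_eta noise intensity (current units x sqrt(time), >= 0).
#' @param seed optional integer seed for the noise stream.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(sigma_eta = 0, seed = NULL) {
  stopifnot(sigma_eta >= 0)
  structure(list(sigma_eta = sigma_eta, seed = seed), class = "noise_params")
}
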