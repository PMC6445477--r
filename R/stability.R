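#' Map network eigenvalues to connectivity eigenvalues (forward map)
#'
#' Every eigenvalue `lambda` of the linearised 2N network dynamics pairs with
#' an eigenvalue `lambda_J` of the connectivity matrix. Synaptic filtering:
#' `lambda_J = (1 + tau_m lambda)(1 + tau_s lambda)`. Adaptation:
#' `lambda_J = 1 + tau_m lambda + g_w / (1 + tau_w lambda)`.
#'
#' @param params a [unit_params()].
#' @param lambda complex vector of network-mode eigenvalues.
#' @return complex vector of connectivity eigenvalues.
#' @export
mode_to_lambda_J <- function(params, lambda) {
  tm <- params$tau_m
  if (params$mechanism == "synaptic") {
    (1 + tm * lambda) * (1 + params$tau_s * lambda)
  } else {
    1 + tm * lambda + params$g_w / (1 + params$tau_w * lambda)
  }
}

#' Map a connectivity eigenvalue to the two network-mode eigenvalues
#'
#' Inverts the forward map by solving its quadratic. Synaptic:
#' `lambda^2 + (1/tau_m + 1/tau_s) lambda + (1 - lambda_J)/(tau_s tau_m) = 0`.
#' Adaptation (in `u = tau_m lambda`): `u^2 + (1 + tau_m/tau_w - lambda_J) u +
#' (tau_m/tau_w)(1 + g_w - lambda_J) = 0`.
#'
#' @param params a [unit_params()].
#' @param lambda_J a complex connectivity eigenvalue (vectorised).
#' @return a 2-column complex matrix of roots, one row per input.
#' @examples
#' p <- unit_params("adaptation", g_w = 0.5, tau_w = 5)
#' map_lambda_J_to_modes(p, 1 + p$g_w)  # one root is 0
#' @export
map_lambda_J_to_modes <- function(params, lambda_J) {
  lambda_J <- as.complex(lambda_J)
  tm <- params$tau_m
  if (params$mechanism == "synaptic") {
    ts <- params$tau_s
    b <- (1 / tm + 1 / ts)
    cc <- (1 - lambda_J) / (ts * tm)
    disc <- sqrt(as.complex(b^2 - 4 * cc))
    cbind((-b + disc) / 2, (-b - disc) / 2)
  } else {
    tw <- params$tau_w
    b <- 1 + tm / tw - lambda_J
    cc <- (tm / tw) * (1 + params$g_w - lambda_J)
    disc <- sqrt(as.complex(b^2 - 4 * cc))
    cbind((-b + disc) / 2, (-b - disc) / 2) / tm
  }
}

#' Heterogeneous stability boundary in the connectivity-eigenvalue plane
#'
#' Image of the imaginary axis `lambda = i omega` of the network-eigenvalue
#' plane under the forward map: the set of connectivity eigenvalues whose
#' network modes are marginal. Synaptic: `(1 + i tau_m omega)(1 + i tau_s
#' omega)`. Adaptation: `1 + i tau_m omega + g_w / (1 + i tau_w omega)`
#' (evaluated from the exact forward map). The curve is conjugate-symmetric
#' under `omega -> -omega`.
#'
#' @param params a [unit_params()].
#' @param omega numeric vector of frequencies (radians per unit time).
#' @return a tibble with columns `omega`, `re`, `im`, `modulus`.
#' @export
boundary_curve <- function(params, omega) {
  lj <- mode_to_lambda_J(params, 1i * omega)
  tibble(omega = omega, re = Re(lj), im = Im(lj), modulus = Mod(lj))
}

#' Critical radius and bifurcation type for heterogeneous perturbations
#'
#' The bulk eigenvalues of the connectivity fill a disk of radius `J_cs`; the
#' fixed point loses stability to heterogeneous perturbations when the disk
#' first touches the stability boundary curve, i.e. at the disk radius
#' `R* = min_omega |lambda_J^sb(omega)|`. The minimiser `omega*` is the
#' frequency of the first unstable mode: `omega* = 0` is a zero-frequency
#' bifurcation (rate chaos), `omega* > 0` a Hopf bifurcation (heterogeneous
#' oscillations). Synaptic filtering always gives `R* = 1` at `omega* = 0`;
#' adaptation gives `R* >= 1`, with a zero-frequency bifurcation iff
#' `tau_m/tau_w > g_w + sqrt(2 g_w (g_w + 1))` (curvature comparison of the
#' boundary parabola against the eigenvalue circle at `omega = 0`).
#'
#' Minimisation uses a dense logarithmic frequency grid (plus `omega = 0`)
#' followed by local refinement, tolerance 1e-8 on `R*`.
#'
#' @param params a [unit_params()].
#' @param n_grid number of grid points.
#' @return an object of class `stability_report`: `critical_radius`,
#'   `critical_frequency`, `bifurcation` (`"zero_frequency"` or `"hopf"`),
#'   `zero_frequency_condition` (the closed-form inequality, adaptation only)
#'   and a sampled `boundary` tibble.
#' @examples
#' p <- unit_params("adaptation", g_w = 0.5, tau_w = 5)
#' critical_radius(p)  # R* ~ 1.114 at omega* ~ 0.448 (Hopf)
#' @export
critical_radius <- function(params, n_grid = 1e5) {
  tm <- params$tau_m
  th <- tau_hidden(params)
  f2 <- function(w) Mod(mode_to_lambda_J(params, 1i * w))^2
  grid <- exp(seq(log(1e-4 / th), log(1e2 / tm), length.out = n_grid))
  vals <- f2(grid)
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(n_grid, k + 1)]
  opt <- optimize(f2, c(lo, hi), tol = 1e-12)
  wstar <- opt$minimum
  fstar <- opt$objective
  # the boundary is smooth at 0; take omega* = 0 whenever it is not beaten
  if (f2(0) <= fstar + 1e-14) {
    wstar <- 0
    fstar <- f2(0)
  }
  zf_cond <- if (params$mechanism == "adaptation") {
    tm / params$tau_w >
      params$g_w + sqrt(2 * params$g_w * (params$g_w + 1))
  } else TRUE
  wplot <- seq(0, 4 * pi / tm, length.out = 801)
  structure(list(
    critical_radius = sqrt(fstar),
    critical_frequency = wstar,
    bifurcation = if (wstar == 0) "zero_frequency" else "hopf",
    zero_frequency_condition = zf_cond,
    boundary = boundary_curve(params, wplot),
    params = params
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s: R* = %.8g at omega* = %.6g (%s)\n",
              x$params$mechanism, x$critical_radius, x$critical_frequency,
              x$bifurcation))
  invisible(x)
}

#' Adaptation coupling above which only a Hopf bifurcation is possible
#'
#' Solves `g_w + sqrt(2 g_w (g_w + 1)) = tau_m / tau_w` at the fastest
#' admissible adaptation, `tau_w = tau_m`, for the coupling above which the
#' zero-frequency branch disappears for every `tau_w > tau_m`. The root is
#' `sqrt(5) - 2 ~ 0.236`.
#'
#' @param tol root-finding tolerance.
#' @return the critical adaptation coupling.
#' @export
hopf_only_coupling <- function(tol = 1e-12) {
  uniroot(function(gw) gw + sqrt(2 * gw * (gw + 1)) - 1,
          c(1e-9, 1), tol = tol)$root
}

#' Full 2N-dimensional Jacobian spectrum of a sampled network
#'
#' Assembles the block Jacobian of the linearised network at the fixed point
#' and computes its dense eigendecomposition. Every eigenvalue must map
#' through the forward map onto an eigenvalue of the connectivity matrix;
#' the maximum mapping mismatch is reported.
#'
#' @param W a `connectivity` object with `N <= 1500`.
#' @param params a [unit_params()].
#' @return an object of class `jacobian_spectrum`: `values` (2N complex),
#'   `connectivity_values` (N complex), `max_mapping_error`, `n_unstable`
#'   (eigenvalues with positive real part beyond 1e-8), `phi_prime`.
#' @export
full_jacobian_spectrum <- function(W, params) {
  stopifnot(inherits(W, "connectivity"))
  N <- nrow(W$weights)
  if (N > 1500) abort("dense 2N eigendecomposition guarded at N <= 1500")
  fp <- fixed_point(params, effective_coupling(W))
  phi_prime <- if (identical(fp$regime, "linear")) 1 else 0
  tm <- params$tau_m
  Wd <- as.matrix(W$weights)
  I_N <- diag(N)
  A <- if (params$mechanism == "synaptic") {
    rbind(cbind(-I_N / tm, I_N / tm),
          cbind(phi_prime * Wd / params$tau_s, -I_N / params$tau_s))
  } else {
    rbind(cbind((phi_prime * Wd - I_N) / tm, -params$g_w * I_N / tm),
          cbind(I_N / params$tau_w, -I_N / params$tau_w))
  }
  vals <- eigen(A, only.values = TRUE)$values
  cvals <- eigen(Wd, only.values = TRUE)$values
  mapped <- mode_to_lambda_J(params, vals)
  err <- vapply(mapped, function(z) min(Mod(z - cvals)), numeric(1))
  structure(list(values = vals, connectivity_values = cvals,
                 max_mapping_error = max(err),
                 n_unstable = sum(Re(vals) > 1e-8),
                 phi_prime = phi_prime, params = params,
                 radius = coupling_radius(W)),
            class = "jacobian_spectrum")
}

#' @export
print.jacobian_spectrum <- function(x, ...) {
  cat(sprintf("<jacobian_spectrum> %d modes, %d unstable; mapping error %.2e\n",
              length(x$values), x$n_unstable, x$max_mapping_error))
  invisible(x)
}

#' Heterogeneous phase diagram over adaptation parameter grids
#'
#' Tabulates the critical radius, bifurcation frequency and type over grids
#' of the adaptation coupling and time constant.
#'
#' @param g_w_grid,tau_w_grid parameter grids.
#' @param tau_m membrane time constant.
#' @param ... passed to [unit_params()] (e.g. `gamma`, `phi_max`).
#' @return a tibble with columns `g_w`, `tau_w`, `critical_radius`,
#'   `critical_frequency`, `bifurcation`.
#' @export
hetero_phase_diagram <- function(g_w_grid, tau_w_grid, tau_m = 1, ...) {
  grid <- expand.grid(g_w = g_w_grid, tau_w = tau_w_grid)
  purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    p <- unit_params("adaptation", tau_m = tau_m, g_w = grid$g_w[k],
                     tau_w = grid$tau_w[k], ...)
    r <- critical_radius(p, n_grid = 2e4)
    tibble(g_w = grid$g_w[k], tau_w = grid$tau_w[k],
           critical_radius = r$critical_radius,
           critical_frequency = r$critical_frequency,
           bifurcation = r$bifurcation)
  })
}
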