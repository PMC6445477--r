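#' Simulate the full 2N-dimensional network dynamics
#'
#' Explicit Euler-Maruyama integration of the coupled current/hidden-variable
#' equations for every unit. The recurrent input `sum_j J_ij phi(x_j)` (plus
#' any external input and the intrinsic white noise) enters the current
#' equation for adaptation and the synaptic equation for synaptic filtering.
#' Adaptation uses the linearised hidden dynamics `tau_w dw = -w + x - gamma`
#' (set `nonlinear_adaptation = TRUE` to low-pass the full rate instead; that
#' variant is exploratory and excluded from the analytic theory).
#'
#' @param W a `connectivity` object.
#' @param params a [unit_params()].
#' @param noise a [noise_params()] (intrinsic white noise intensity).
#' @param T total integration time.
#' @param dt time step; must satisfy `dt <= 0.1 min(tau_m, tau_hidden)`.
#' @param init `"fixed_point"` (equilibrium plus an i.i.d. uniform current
#'   perturbation of half-width `perturbation`) or a list with numeric
#'   vectors `x` and `hidden`.
#' @param perturbation half-width of the initial uniform current perturbation.
#' @param I_ext optional external input: a length-N vector (constant in time)
#'   or an N x nsteps matrix.
#' @param seed integer seed controlling the initial perturbation and the
#'   noise stream.
#' @param store_every store every k-th step (thinning).
#' @return an object of class `trajectory`: `times`, `x` and `hidden`
#'   (N x n_stored matrices), `dt`, `params`, `mechanism`, `seed`.
#' @examples
#' W <- build_connectivity(connectivity_spec(N = 100, C_E = 8, C_I = 2,
#'                                           radius = 0.8, seed = 3))
#' p <- unit_params("synaptic", tau_s = 5)
#' tr <- simulate_network(W, p, T = 20, dt = 0.05, seed = 1)
#' @export
simulate_network <- function(W, params, noise = noise_params(0), T, dt,
                             init = "fixed_point", perturbation = 0.01,
                             I_ext = NULL, seed = NULL, store_every = 1L,
                             nonlinear_adaptation = FALSE) {
  stopifnot(inherits(W, "connectivity"), inherits(params, "unit_params"))
  th <- tau_hidden(params)
  if (dt > 0.1 * min(params$tau_m, th) + 1e-12)
    abort(sprintf("dt = %g too large; need dt <= 0.1 * min(tau_m, tau_hidden) = %g",
                  dt, 0.1 * min(params$tau_m, th)))
  N <- nrow(W$weights)
  nsteps <- round(T / dt)
  J_eff <- effective_coupling(W)

  state <- if (is.list(init)) {
    stopifnot(length(init$x) == N, length(init$hidden) == N)
    list(x = init$x, hidden = init$hidden)
  } else if (identical(init, "fixed_point")) {
    fp <- fixed_point(params, J_eff)
    if (is.na(fp$x0)) abort("no valid fixed point to initialise from")
    x0 <- rep(fp$x0, N)
    h0 <- if (params$mechanism == "adaptation") x0 - params$gamma
          else rep(J_eff * fp$rate0, N)
    list(x = x0, hidden = h0)
  } else abort("init must be \"fixed_point\" or a list(x=, hidden=)")

  res <- with_seed(seed, {
    if (!is.list(init) && perturbation > 0)
      state$x <- state$x + runif(N, -perturbation, perturbation)
    Iext_mat <- matrix(0, 0, 0)
    has_input <- !is.null(I_ext)
    if (has_input) {
      Iext_mat <- if (is.matrix(I_ext)) I_ext else matrix(I_ext, N, 1)
      stopifnot(nrow(Iext_mat) == N)
    }
    cpp_simulate_network(W$weights, mech_code(params), params$tau_m, th,
                         params$g_w %||% 0, params$gamma, params$phi_max,
                         state$x, state$hidden, nsteps, dt, noise$sigma_eta,
                         Iext_mat, has_input, as.integer(store_every),
                         nonlinear_adaptation)
  })
  if (isTRUE(res$error))
    abort(sprintf("integration blew up (non-finite state) at t = %g (step %d)",
                  res$time, res$step))
  times <- seq(0, by = dt * store_every, length.out = ncol(res$x))
  structure(list(times = times, x = res$x, hidden = res$hidden,
                 dt = dt, store_every = as.integer(store_every),
                 params = params, mechanism = params$mechanism,
                 noise = noise, seed = seed, J_eff = J_eff,
                 radius = coupling_radius(W)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s network: N = %d units, t in [0, %.4g], dt = %g (stored every %d)\n",
              x$mechanism, nrow(x$x), max(x$times), x$dt, x$store_every))
  invisible(x)
}

#' Firing rates of a simulated trajectory
#'
#' @param traj a `trajectory`.
#' @return an N x n_stored matrix of rates `phi(x)`.
#' @export
unit_rates <- function(traj) {
  transfer(traj$x, traj$params$gamma, traj$params$phi_max)
}

#' Population-averaged rate time series
#'
#' @param traj a `trajectory`.
#' @return a tibble with columns `time` and `rate` (mean rate across units).
#' @export
population_average <- function(traj) {
  tibble(time = traj$times, rate = colMeans(unit_rates(traj)))
}
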