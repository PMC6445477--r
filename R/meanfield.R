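#' Population-averaged fixed points
#'
#' Scans the three transfer regimes for self-consistent equilibria of the
#' population-averaged current. For synaptic filtering the equilibrium solves
#' `x0 = J_eff phi(x0)`; for adaptation `(1 + g_w) x0 = J_eff phi(x0) +
#' g_w gamma`. Closed forms per regime (validated against the regime bounds):
#' silent `phi = 0`; linear `x0 = -J_eff gamma / (1 - J_eff)` (synaptic) or
#' `x0 = gamma (g_w - J_eff) / (1 + g_w - J_eff)` (adaptation); saturated
#' `x0 = J_eff phi_max` (synaptic) or `(J_eff phi_max + g_w gamma)/(1 + g_w)`
#' (adaptation), valid when `x0 >= gamma + phi_max`.
#'
#' @param params a [unit_params()].
#' @param J_eff effective recurrent coupling `J (C_E - g C_I)`.
#' @return an object of class `fixed_points`: primary `x0`, `rate0`, `regime`,
#'   and a tibble `solutions` with every candidate and its validity.
#' @examples
#' fixed_point(unit_params("synaptic", tau_s = 5), J_eff = -2)
#' @export
fixed_point <- function(params, J_eff) {
  stopifnot(inherits(params, "unit_params"))
  gam <- params$gamma
  pm <- params$phi_max
  adapt <- params$mechanism == "adaptation"
  gw <- if (adapt) params$g_w else 0
  tol <- 1e-12

  cand <- list()
  # silent: phi = 0
  x_sil <- if (adapt) gw * gam / (1 + gw) else 0
  cand$silent <- c(x_sil, valid = x_sil <= gam + tol)
  # linear: phi = x - gamma
  den <- 1 + gw - J_eff
  if (abs(den) > tol) {
    x_lin <- gam * (gw - J_eff) / den
    cand$linear <- c(x_lin, valid = x_lin > gam + tol && x_lin < gam + pm - tol)
  }
  # saturated: phi = phi_max
  x_sat <- (J_eff * pm + gw * gam) / (1 + gw)
  cand$saturated <- c(x_sat, valid = x_sat >= gam + pm - tol)

  sol <- tibble(
    regime = names(cand),
    x0 = unname(vapply(cand, `[`, numeric(1), 1)),
    valid = unname(vapply(cand, function(z) as.logical(z[2]), logical(1)))
  )
  sol$rate0 <- transfer(sol$x0, gam, pm)
  # each branch must satisfy its defining equation with the branch's phi
  phi_branch <- c(silent = 0, linear = NA, saturated = pm)[sol$regime]
  phi_branch[sol$regime == "linear"] <- sol$x0[sol$regime == "linear"] - gam
  resid <- (1 + gw) * sol$x0 - J_eff * phi_branch - gw * gam
  stopifnot(all(abs(resid) < 1e-10))
  sol <- sol[, c("x0", "rate0", "regime", "valid")]

  vsol <- sol[sol$valid, ]
  primary <- if (any(vsol$regime == "linear")) {
    vsol[vsol$regime == "linear", ]
  } else if (nrow(vsol) > 0) vsol[1, ] else NULL
  structure(list(
    x0 = if (is.null(primary)) NA_real_ else primary$x0,
    rate0 = if (is.null(primary)) NA_real_ else primary$rate0,
    regime = if (is.null(primary)) NA_character_ else primary$regime,
    solutions = sol, J_eff = J_eff, params = params
  ), class = "fixed_points")
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(sprintf("<fixed_points> J_eff = %.4g: primary %s at x0 = %.6g (rate %.6g)\n",
              x$J_eff, x$regime, x$x0, x$rate0))
  print(x$solutions)
  invisible(x)
}

#' Population-averaged 2x2 dynamic matrix
#'
#' Jacobian of the homogeneous (population-averaged) linearised dynamics.
#' Synaptic: `(1/tau_m) [[-1, 1], [phi' J_eff tau_m/tau_s, -tau_m/tau_s]]`;
#' adaptation: `(1/tau_m) [[-1 + phi' J_eff, -g_w], [tau_m/tau_w,
#' -tau_m/tau_w]]`. With `J_eff = 0` or `phi' = 0` this reduces to the
#' single-unit dynamic matrix.
#'
#' @inheritParams fixed_point
#' @param phi_prime transfer derivative at the fixed point (0 or 1).
#' @return a numeric 2x2 matrix.
#' @export
popavg_jacobian <- function(params, J_eff, phi_prime = 1) {
  stopifnot(inherits(params, "unit_params"), phi_prime %in% c(0, 1))
  tm <- params$tau_m
  if (params$mechanism == "synaptic") {
    ts <- params$tau_s
    matrix(c(-1, phi_prime * J_eff * tm / ts, 1, -tm / ts), 2, 2) / tm
  } else {
    tw <- params$tau_w
    matrix(c(-1 + phi_prime * J_eff, tm / tw, -params$g_w, -tm / tw), 2, 2) / tm
  }
}

classify_2x2 <- function(tr, dt, tol = 1e-9) {
  if (abs(dt) < tol || (dt > 0 && abs(tr) < tol)) return("marginal")
  if (dt < 0) return("saddle_node_unstable")
  if (tr > 0) return("hopf_unstable")
  "stable"
}

#' Stability of the population-averaged dynamics
#'
#' Classifies the homogeneous-perturbation dynamics from the trace and
#' determinant of the 2x2 dynamic matrix at the fixed point. Synaptic
#' networks are stable iff `J_eff < 1` (saddle-node at `J_eff = 1`, for any
#' time constants). Adaptive networks are stable iff `J_eff < min(1 + g_w,
#' 1 + tau_m/tau_w)`; the active boundary is a Hopf bifurcation when
#' `tau_m/tau_w < g_w`, a saddle-node otherwise. Fixed points outside the
#' linear regime have `phi' = 0` and reduce to the always-stable single-unit
#' dynamics.
#'
#' @inheritParams fixed_point
#' @return an object of class `popavg_report`: `jacobian`, `eigen`
#'   (`eigen_pair`), `classification`, `critical_couplings` (named vector,
#'   with the active boundary as attribute), `phi_prime`, `fixed_point`, and
#'   the exact population-averaged impulse-response `filter`.
#' @examples
#' popavg_stability(unit_params("adaptation", g_w = 2, tau_w = 5), J_eff = 1)
#' @export
popavg_stability <- function(params, J_eff) {
  fp <- fixed_point(params, J_eff)
  phi_prime <- if (identical(fp$regime, "linear")) 1 else 0
  tm <- params$tau_m
  crit_min <- if (params$mechanism == "synaptic") 1
              else min(1 + params$g_w, 1 + tm / tau_hidden(params))
  # exactly at the critical coupling the linear equilibrium degenerates (it
  # runs off to infinity at a saddle-node); classify the linear-regime
  # dynamics there so the boundary is reported as marginal
  if (phi_prime == 0 && abs(J_eff - crit_min) < 1e-9) phi_prime <- 1
  A <- popavg_jacobian(params, J_eff, phi_prime)
  ep <- eigen_pair_2x2(A)
  tr <- A[1, 1] + A[2, 2]
  dt <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  cls <- classify_2x2(tr, dt)
  if (params$mechanism == "synaptic") {
    crit <- c(saddle_node = 1)
    active <- "saddle_node"
    filt <- propagator_filter(A, 1, 2, gain = 1 / params$tau_s,
                              mechanism = "synaptic")
  } else {
    crit <- c(saddle_node = 1 + params$g_w, hopf = 1 + tm / params$tau_w)
    active <- names(crit)[which.min(crit)]
    filt <- propagator_filter(A, 1, 1, gain = 1 / tm,
                              mechanism = "adaptation")
  }
  attr(crit, "active") <- active
  structure(list(jacobian = A, eigen = ep, classification = cls,
                 critical_couplings = crit, trace = tr, determinant = dt,
                 phi_prime = phi_prime, fixed_point = fp, filter = filt,
                 params = params, J_eff = J_eff),
            class = "popavg_report")
}

#' @export
print.popavg_report <- function(x, ...) {
  cat(sprintf("<popavg_report> %s, J_eff = %.4g: %s\n",
              x$params$mechanism, x$J_eff, x$classification))
  cat(sprintf("  trace = %.6g, det = %.6g, eigenvalues %s, %s\n",
              x$trace, x$determinant,
              format(x$eigen$values[1], digits = 5),
              format(x$eigen$values[2], digits = 5)))
  cat("  critical couplings:",
      paste(names(x$critical_couplings),
            signif(x$critical_couplings, 6), sep = " = ", collapse = ", "),
      sprintf("(active: %s)\n", attr(x$critical_couplings, "active")))
  invisible(x)
}

#' Slow-limit timescales of the population-averaged activity
#'
#' First-order expressions when the hidden time constant is much slower than
#' the membrane. Synaptic: `tau+ = tau_s / (1 - J_eff)` (slow mode, grows with
#' `tau_s`) and `tau- = tau_m / (1 + J_eff tau_m/tau_s)` (membrane mode, from
#' the eigenvalue expansion `lambda- = -1/tau_m - J_eff/tau_s`). Adaptation:
#' `tau+ = tau_m / (1 - J_eff)` (membrane mode, tunable to arbitrarily slow
#' values near the bifurcation) and `tau- = tau_w (1 - J_eff) /
#' (1 + g_w - J_eff)` (adaptation mode). The area of the adaptive slow mode
#' tends to `-g_w / ((J_eff - 1)(J_eff - 1 - g_w))`, independent of `tau_w`.
#'
#' @inheritParams fixed_point
#' @return a list of class `slow_limit`: `tau_plus`, `tau_minus`,
#'   `slow_mode_area` (the limiting closed form), `exact_slow_mode_area` (from
#'   the exact population-averaged filter at the given parameters), and the
#'   exact `filter`.
#' @export
popavg_slow_limit <- function(params, J_eff) {
  rep_ <- popavg_stability(params, J_eff)
  if (rep_$classification != "stable" || rep_$phi_prime != 1)
    abort("slow-limit timescales require a stable linear-regime configuration")
  tm <- params$tau_m
  filt <- rep_$filter
  # slow mode = mode with the smallest |Re lambda|
  ks <- which.min(abs(Re(filt$lambda)))
  exact_area <- Re(filt$a[ks] / (-filt$lambda[ks]))
  if (params$mechanism == "synaptic") {
    ts <- params$tau_s
    out <- list(tau_plus = ts / (1 - J_eff),
                tau_minus = tm / (1 + J_eff * tm / ts),
                slow_mode_area = NA_real_)
  } else {
    tw <- params$tau_w
    gw <- params$g_w
    out <- list(tau_plus = tm / (1 - J_eff),
                tau_minus = tw * (1 - J_eff) / (1 + gw - J_eff),
                slow_mode_area = -gw / ((J_eff - 1) * (J_eff - 1 - gw)))
  }
  out$exact_slow_mode_area <- exact_area
  out$filter <- filt
  out$mechanism <- params$mechanism
  structure(out, class = "slow_limit")
}

#' Saddle-node coupling of the population-averaged dynamics
#'
#' Locates the zero crossing of the determinant of the population-averaged
#' dynamic matrix as a function of the effective coupling, by bisection. For
#' synaptic filtering the crossing sits at `J_eff = 1` for any time
#' constants; for adaptation at `J_eff = 1 + g_w`.
#'
#' @param params a [unit_params()].
#' @param interval search interval for `J_eff`.
#' @param tol bisection tolerance.
#' @return the critical effective coupling.
#' @export
popavg_saddle_node <- function(params, interval = c(0, 2), tol = 1e-12) {
  det_at <- function(J_eff) {
    A <- popavg_jacobian(params, J_eff, phi_prime = 1)
    A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  }
  uniroot(det_at, interval, tol = tol)$root
}

#' Phase diagram of the population-averaged dynamics on a parameter grid
#'
#' @param params a [unit_params()] providing the mechanism and time constants.
#' @param j_eff_grid effective couplings to scan.
#' @param g_w_grid adaptation couplings to scan (adaptation only; defaults to
#'   the single value in `params`).
#' @return a tibble with one row per grid point: `j_eff`, `g_w` (if
#'   relevant), `classification`, `regime`.
#' @export
popavg_phase_diagram <- function(params, j_eff_grid, g_w_grid = NULL) {
  if (params$mechanism == "synaptic" || is.null(g_w_grid)) {
    rows <- purrr::map(j_eff_grid, function(j) {
      r <- popavg_stability(params, j)
      tibble(j_eff = j, g_w = params$g_w %||% NA_real_,
             classification = r$classification,
             regime = r$fixed_point$regime)
    })
  } else {
    grid <- expand.grid(j_eff = j_eff_grid, g_w = g_w_grid)
    rows <- purrr::map(seq_len(nrow(grid)), function(k) {
      p <- unit_params("adaptation", tau_m = params$tau_m,
                       g_w = grid$g_w[k], tau_w = params$tau_w,
                       gamma = params$gamma, phi_max = params$phi_max)
      r <- popavg_stability(p, grid$j_eff[k])
      tibble(j_eff = grid$j_eff[k], g_w = grid$g_w[k],
             classification = r$classification,
             regime = r$fixed_point$regime)
    })
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
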