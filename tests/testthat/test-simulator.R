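test_that("the fixed point is invariant under noise-free integration", {
  W <- small_net(N = 100, radius = 0.8, seed = 3, C_E = 8, C_I = 2)
  for (p in list(p_syn(tau_s = 5), p_adapt(g_w = 0.5, tau_w = 5))) {
    fp <- fixed_point(p, effective_coupling(W))
    tr <- simulate_network(W, p, T = 100, dt = 0.05, perturbation = 0, seed = 1)
    expect_lt(max(abs(tr$x - fp$x0)), 1e-8)
  }
})

test_that("subcritical perturbations decay; dt guard and blow-up are raised", {
  W <- small_net(N = 200, radius = 0.8, seed = 11)
  p <- p_syn(tau_s = 5)
  fp <- fixed_point(p, effective_coupling(W))
  tr <- simulate_network(W, p, T = 60, dt = 0.02, perturbation = 1e-3,
                         seed = 2)
  dev <- colSums((tr$x - fp$x0)^2)
  k <- length(dev)
  expect_lt(dev[k], 1e-4 * dev[1])
  # deviation decays monotonically after a short transient
  late <- dev[tr$times > 5]
  expect_true(all(diff(late) < 1e-12))
  expect_error(simulate_network(W, p, T = 1, dt = 0.2), "dt")
})

test_that("integration is deterministic given a seed, including the noise stream", {
  W <- small_net(N = 50, radius = 0.5, seed = 2, C_E = 8, C_I = 2)
  p <- p_adapt(g_w = 0.5, tau_w = 2)
  a <- simulate_network(W, p, noise = noise_params(0.1), T = 10, dt = 0.05,
                        seed = 7)
  b <- simulate_network(W, p, noise = noise_params(0.1), T = 10, dt = 0.05,
                        seed = 7)
  c <- simulate_network(W, p, noise = noise_params(0.1), T = 10, dt = 0.05,
                        seed = 8)
  expect_identical(a$x, b$x)
  expect_false(identical(a$x, c$x))
})

test_that("Euler convergence is first order in dt", {
  W <- small_net(N = 100, radius = 1.2, seed = 5, C_E = 8, C_I = 2)
  p <- p_syn(tau_s = 5)
  ends <- lapply(c(0.04, 0.02, 0.01), function(dt) {
    tr <- simulate_network(W, p, T = 10, dt = dt, perturbation = 0.01,
                           seed = 9)
    tr$x[, ncol(tr$x)]
  })
  d1 <- sqrt(sum((ends[[1]] - ends[[3]])^2))
  d2 <- sqrt(sum((ends[[2]] - ends[[3]])^2))
  # (e(dt) - e(dt/4)) / (e(dt/2) - e(dt/4)) -> 3 for a first-order scheme
  expect_gt(d1 / d2, 2.2)
  expect_lt(d1 / d2, 3.8)
})

test_that("a tiny homogeneous kick decays at the population-averaged eigenvalue rates", {
  W <- small_net(N = 200, radius = 0.6, seed = 13)
  for (p in list(p_syn(tau_s = 5), p_adapt(g_w = 0.5, tau_w = 5))) {
    J_eff <- effective_coupling(W)
    fp <- fixed_point(p, J_eff)
    h0 <- if (p$mechanism == "adaptation") rep(fp$x0 - p$gamma, 200)
          else rep(J_eff * fp$rate0, 200)
    tr <- simulate_network(W, p, T = 30, dt = 0.01,
                           init = list(x = rep(fp$x0 + 1e-4, 200),
                                       hidden = h0))
    # fit the 2x2 dynamic matrix from the population-averaged deviations
    dx <- colMeans(tr$x) - fp$x0
    dh <- colMeans(tr$hidden) - mean(h0)
    Z <- rbind(dx, dh)
    n <- ncol(Z)
    Zdot <- (Z[, 2:n] - Z[, 1:(n - 1)]) / 0.01
    Zmid <- (Z[, 2:n] + Z[, 1:(n - 1)]) / 2
    Ahat <- Zdot %*% t(Zmid) %*% solve(Zmid %*% t(Zmid))
    lam_hat <- sort(Re(eigen(Ahat)$values))
    lam_th <- sort(Re(popavg_stability(p, J_eff)$eigen$values))
    expect_lt(max(abs(lam_hat - lam_th) / abs(lam_th)), 0.02)
  }
})

test_that("supercritical synaptic networks fluctuate heterogeneously, not homogeneously", {
  W <- build_connectivity(connectivity_spec(N = 400, C_E = 16, C_I = 4,
                                            radius = 1.25, g = 4.1,
                                            seed = 17))
  p <- p_syn(tau_s = 5)
  tr <- simulate_network(W, p, T = 250, dt = 0.05, perturbation = 0.1,
                         seed = 3, store_every = 4)
  late <- tr$times > 100
  r <- unit_rates(tr)[, late]
  unit_var <- mean(apply(r, 1, stats::var))
  pop_var <- stats::var(colMeans(r))
  expect_gt(unit_var, 1e-3)
  expect_gt(unit_var, 10 * pop_var)
})

test_that("beyond the adaptive Hopf radius single units oscillate out of phase", {
  W <- build_connectivity(connectivity_spec(N = 1000, C_E = 16, C_I = 4,
                                            radius = 1.35, g = 4.1,
                                            seed = 19))
  p <- p_adapt(g_w = 0.5, tau_w = 5)
  tr <- simulate_network(W, p, T = 650, dt = 0.05, perturbation = 0.1,
                         seed = 5, store_every = 4)
  late <- tr$times > 150
  r <- unit_rates(tr)[, late]
  # oscillation amplitude = spectral amplitude in a band around the Hopf
  # frequency (slow population wander lives at much lower frequencies)
  wstar <- critical_radius(p, n_grid = 2e4)$critical_frequency
  band_amp <- function(z) {
    z <- z - mean(z)
    n <- length(z)
    freq <- 2 * pi * (0:(n - 1)) / (n * 0.2)
    keep <- freq > 0.6 * wstar & freq < 1.6 * wstar
    sqrt(sum(Mod(fft(z))[keep]^2) / n^2)
  }
  amp_unit <- mean(apply(r, 1, band_amp))
  amp_pop <- band_amp(colMeans(r))
  expect_gt(amp_unit, 5 * amp_pop)
})

test_that("marginal oscillation frequency matches the unstable pair at the Hopf point", {
  # pick a finite matrix with exactly one unstable conjugate pair
  p <- p_adapt(g_w = 0.5, tau_w = 5)
  W <- NULL
  for (sd in 1:40) {
    cand <- build_connectivity(connectivity_spec(N = 200, C_E = 16, C_I = 4,
                                                 radius = 1.17, g = 4.1,
                                                 seed = sd))
    js <- full_jacobian_spectrum(cand, p)
    if (js$n_unstable == 2 && all(abs(Im(js$values[Re(js$values) > 1e-8])) >
                                    1e-4)) {
      W <- cand
      lam_u <- js$values[Re(js$values) > 1e-8]
      break
    }
  }
  expect_false(is.null(W))
  tr <- simulate_network(W, p, T = 900, dt = 0.02, perturbation = 1e-3,
                         seed = 2, store_every = 5)
  late <- tr$times > 300
  x1 <- tr$x[which.max(apply(tr$x[, late], 1, stats::var)), late]
  x1 <- x1 - mean(x1)
  n <- length(x1)
  sp <- Mod(fft(x1))[1:(n %/% 2)]
  k <- which.max(sp[-1]) + 1
  # parabolic interpolation of the spectral peak
  num <- log(sp[k - 1]) - log(sp[k + 1])
  den <- log(sp[k - 1]) - 2 * log(sp[k]) + log(sp[k + 1])
  kf <- (k - 1) + 0.5 * num / den
  f_peak <- 2 * pi * kf / (n * 0.1)
  expect_lt(abs(f_peak - abs(Im(lam_u[1]))) / abs(Im(lam_u[1])), 0.05)
})

test_that("population average is permutation invariant and exact for constant rates", {
  W <- small_net(N = 60, radius = 0.5, seed = 23, C_E = 8, C_I = 2)
  p <- p_syn(tau_s = 2)
  tr <- simulate_network(W, p, T = 20, dt = 0.05, perturbation = 0.05,
                         seed = 31)
  pa <- population_average(tr)
  tr2 <- tr
  perm <- sample(60)
  tr2$x <- tr$x[perm, ]
  tr2$hidden <- tr$hidden[perm, ]
  expect_equal(population_average(tr2)$rate, pa$rate)
  # constant rates give the same constant
  tr3 <- tr
  tr3$x <- matrix(0.2, nrow = 60, ncol = ncol(tr$x))
  expect_true(all(population_average(tr3)$rate == transfer(0.2)))
})

test_that("external input drives the expected steady-state shift", {
  W <- small_net(N = 100, radius = 0.5, seed = 29, C_E = 8, C_I = 2)
  p <- p_syn(tau_s = 2)
  J_eff <- effective_coupling(W)
  fp <- fixed_point(p, J_eff)
  I0 <- 0.05
  tr <- simulate_network(W, p, T = 80, dt = 0.02, perturbation = 0,
                         I_ext = rep(I0, 100), seed = 1)
  # linear steady state: dx = I0 / (1 - J_eff) while still in the linear regime
  expect_equal(mean(tr$x[, ncol(tr$x)]), fp$x0 + I0 / (1 - J_eff),
               tolerance = 1e-3)
})
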