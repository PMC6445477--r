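test_that("fixed points solve their transcendental equations in every regime", {
  # synaptic linear-regime closed form
  fp <- fixed_point(p_syn(), J_eff = -2)
  expect_equal(fp$x0, -1 / 3, tolerance = 1e-12)
  expect_equal(fp$rate0, 1 / 6, tolerance = 1e-12)
  expect_identical(fp$regime, "linear")
  # adaptive linear-regime closed form
  fpa <- fixed_point(p_adapt(g_w = 0.5), J_eff = -2)
  expect_equal(fpa$x0, -0.5 * 2.5 / 3.5, tolerance = 1e-12)
  expect_equal(fpa$rate0, 1 / 7, tolerance = 1e-12)
  # g_w = 0 reduces the adaptive equation to the synaptic one
  set.seed(8)
  for (k in 1:20) {
    J <- runif(1, -4, 0.9)
    gam <- runif(1, -1, -0.1)
    ps <- unit_params("synaptic", tau_s = 2, gamma = gam)
    pa <- unit_params("adaptation", g_w = 0, tau_w = 2, gamma = gam)
    expect_equal(fixed_point(pa, J)$x0, fixed_point(ps, J)$x0,
                 tolerance = 1e-12)
  }
  # saturated solution appears beyond the saddle-node and is validated
  fps <- fixed_point(p_syn(), J_eff = 1.5)
  sat <- fps$solutions[fps$solutions$regime == "saturated", ]
  expect_true(sat$valid)
  expect_equal(sat$x0, 3)
  # empty-solution case is reported, not raised
  hollow <- fixed_point(unit_params("synaptic", tau_s = 1, gamma = -0.5,
                                    phi_max = 0.4), J_eff = 1.2)
  expect_true(is.data.frame(hollow$solutions))
})

test_that("adaptive equilibrium rate decreases with the adaptation coupling", {
  for (J in c(-3, -1, 0.5)) {
    rates <- vapply(seq(0, 4, 0.25), function(gw)
      fixed_point(p_adapt(g_w = gw, tau_w = 5), J)$rate0, numeric(1))
    expect_true(all(diff(rates) < 0))
  }
})

test_that("population-averaged Jacobian: reductions and closed-form arithmetic", {
  # J_eff = 0 or phi' = 0 reduces to the single-unit matrix
  p <- p_syn(tau_s = 4)
  A0 <- popavg_jacobian(p, 0)
  expect_equal(A0, matrix(c(-1, 0, 1, -0.25), 2, 2))
  expect_equal(popavg_jacobian(p, -3, phi_prime = 0), A0)
  # adaptive trace/determinant arithmetic
  A <- popavg_jacobian(p_adapt(g_w = 0.5, tau_w = 5), -2)
  expect_equal(sum(diag(A)), -3.2, tolerance = 1e-12)
  expect_equal(det(A), 0.7, tolerance = 1e-12)
  # numeric eigenvalues match the closed-form 2x2 solutions for random draws
  set.seed(12)
  for (k in 1:100) {
    adapt <- k %% 2 == 0
    p <- if (adapt) p_adapt(g_w = runif(1, 0, 3), tau_w = runif(1, 1, 30))
         else p_syn(tau_s = runif(1, 1, 30))
    J <- runif(1, -4, 0.9)
    A <- popavg_jacobian(p, J)
    ep <- ratenet:::eigen_pair_2x2(A)
    ev <- eigen(A)$values
    expect_lt(max(abs(sort(Re(ep$values)) - sort(Re(ev)))), 1e-12)
    expect_lt(max(abs(sort(Im(ep$values)) - sort(Im(ev)))), 1e-12)
  }
})

test_that("popavg stability boundaries: synaptic saddle-node, adaptive min rule", {
  # synaptic marginal exactly at J_eff = 1, determinant zero
  r <- popavg_stability(p_syn(tau_s = 3), 1)
  expect_identical(r$classification, "marginal")
  expect_equal(r$determinant, 0, tolerance = 1e-12)
  # stability iff J_eff < 1, any time constants; beyond the bifurcation the
  # linear-regime Jacobian is saddle-unstable and the system settles on the
  # (stable) saturated fixed point
  for (ts in c(0.5, 2, 50)) {
    expect_identical(popavg_stability(p_syn(tau_s = ts), 0.99)$classification,
                     "stable")
    beyond <- popavg_stability(p_syn(tau_s = ts), 1.2)
    expect_identical(beyond$fixed_point$regime, "saturated")
    expect_identical(beyond$classification, "stable")
    Alin <- popavg_jacobian(p_syn(tau_s = ts), 1.2, phi_prime = 1)
    expect_lt(det(Alin), 0)
  }
  # adaptive: Hopf boundary active when tau_m/tau_w < g_w
  r2 <- popavg_stability(p_adapt(g_w = 2, tau_w = 5), 1)
  expect_equal(as.numeric(r2$critical_couplings), c(3, 1.2))
  expect_identical(attr(r2$critical_couplings, "active"), "hopf")
  expect_identical(popavg_stability(p_adapt(g_w = 2, tau_w = 5),
                                    1.3)$classification, "hopf_unstable")
  # saddle-node active when tau_m/tau_w > g_w
  r3 <- popavg_stability(p_adapt(g_w = 0.1, tau_w = 2), 1.05)
  expect_identical(attr(r3$critical_couplings, "active"), "saddle_node")
  expect_equal(min(r3$critical_couplings), 1.1)
  expect_identical(r3$classification, "stable")
})

test_that("slow-limit timescales match the eigenvalue expansions and tighten as the slow constant doubles", {
  # arithmetic of the closed forms
  sl <- popavg_slow_limit(p_syn(tau_s = 100), -2)
  expect_equal(sl$tau_plus, 100 / 3, tolerance = 1e-12)
  sla <- popavg_slow_limit(p_adapt(g_w = 0.5, tau_w = 100), -2)
  expect_equal(sla$tau_plus, 1 / 3, tolerance = 1e-12)
  expect_equal(sla$slow_mode_area, -0.5 / (3 * 3.5), tolerance = 1e-12)
  # asymptotic consistency: |1/tau_hat - |Re lambda|| halves when tau doubles
  err_syn <- vapply(c(25, 50, 100, 200), function(ts) {
    r <- popavg_stability(p_syn(tau_s = ts), -2)
    sl <- popavg_slow_limit(p_syn(tau_s = ts), -2)
    lam <- r$eigen$values
    slow <- lam[which.min(abs(Re(lam)))]
    fast <- lam[which.max(abs(Re(lam)))]
    max(abs(1 / sl$tau_plus - abs(Re(slow))),
        abs(1 / sl$tau_minus - abs(Re(fast))))
  }, numeric(1))
  expect_true(all(diff(err_syn) < 0))
  expect_true(all(err_syn[-1] / head(err_syn, -1) < 0.6))
  err_ad <- vapply(c(25, 50, 100, 200), function(tw) {
    r <- popavg_stability(p_adapt(g_w = 0.5, tau_w = tw), -2)
    sl <- popavg_slow_limit(p_adapt(g_w = 0.5, tau_w = tw), -2)
    lam <- r$eigen$values
    slow <- lam[which.min(abs(Re(lam)))]   # adaptation mode ~ 1/tau_w
    fast <- lam[which.max(abs(Re(lam)))]
    max(abs(1 / sl$tau_minus - abs(Re(slow))),
        abs(1 / sl$tau_plus - abs(Re(fast))))
  }, numeric(1))
  expect_true(all(err_ad[-1] / head(err_ad, -1) < 0.6))
  # adaptive popavg slow-mode area approaches its tau_w-free limit,
  # error halving as tau_w doubles
  area_err <- vapply(c(50, 100, 200), function(tw) {
    sl <- popavg_slow_limit(p_adapt(g_w = 0.5, tau_w = tw), -2)
    abs(sl$exact_slow_mode_area - sl$slow_mode_area)
  }, numeric(1))
  expect_true(all(area_err[-1] / head(area_err, -1) < 0.6))
  # unstable configurations refuse a slow limit
  expect_error(popavg_slow_limit(p_syn(tau_s = 5), 1.5), "linear-regime")
})

test_that("synaptic popavg filter has equal-magnitude opposite-sign amplitudes", {
  for (cfg in list(c(5, -2), c(50, -0.5), c(8, 0.5))) {
    r <- popavg_stability(p_syn(tau_s = cfg[1]), cfg[2])
    a <- r$filter$a
    expect_equal(Mod(a[1]), Mod(a[2]), tolerance = 1e-12)
    expect_equal(sum(Re(a)), 0, tolerance = 1e-12)
  }
})

test_that("popavg phase diagram labels a grid consistently with pointwise classification", {
  pd <- popavg_phase_diagram(p_adapt(g_w = 1, tau_w = 5),
                             j_eff_grid = c(-1, 1.1, 1.5, 2.5),
                             g_w_grid = c(0.1, 1))
  expect_equal(nrow(pd), 8)
  one <- popavg_stability(p_adapt(g_w = 0.1, tau_w = 5), 1.5)
  expect_identical(pd$classification[pd$g_w == 0.1 & pd$j_eff == 1.5],
                   one$classification)
})
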