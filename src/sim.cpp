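#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// threshold-linear transfer with saturation
static inline double phi_fun(double x, double gamma, double phi_max) {
  double r = x - gamma;
  if (r < 0.0) return 0.0;
  return r > phi_max ? phi_max : r;
}

// Euler-Maruyama integration of the full 2N network.
// mech: 0 = adaptation (hidden w, input and noise enter the current equation),
//       1 = synaptic filtering (hidden s, input and noise enter the synaptic equation).
// Noise convention: <eta(t) eta(t')> = (sigma_eta^2 / 2) delta(t - t'), so the
// per-step increment on the driven equation is (sigma_eta / tau) * sqrt(dt / 2) * z.
// [[Rcpp::export]]
List cpp_simulate_network(const arma::sp_mat& W, int mech,
                          double tau_m, double tau_h, double g_w,
                          double gamma, double phi_max,
                          arma::vec x, arma::vec hid,
                          int nsteps, double dt, double sigma_eta,
                          const arma::mat& I_ext, bool has_input,
                          int store_every, bool nonlinear_adapt) {
  const int N = x.n_elem;
  const int nstore = nsteps / store_every + 1;
  arma::mat X(N, nstore), H(N, nstore);
  X.col(0) = x;
  H.col(0) = hid;
  arma::vec phi(N), rec(N);
  const double noise_sd = sigma_eta * std::sqrt(dt / 2.0);
  int si = 1;
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < N; ++i) phi[i] = phi_fun(x[i], gamma, phi_max);
    rec = W * phi;
    if (has_input) {
      int col = s - 1;
      if (col >= (int)I_ext.n_cols) col = I_ext.n_cols - 1;
      rec += I_ext.col(col);
    }
    if (mech == 0) {
      for (int i = 0; i < N; ++i) {
        double nx = x[i] + dt * (-x[i] - g_w * hid[i] + rec[i]) / tau_m;
        if (sigma_eta > 0.0) nx += noise_sd / tau_m * norm_rand();
        double target = nonlinear_adapt ? phi_fun(x[i], gamma, phi_max)
                                        : (x[i] - gamma);
        hid[i] += dt * (-hid[i] + target) / tau_h;
        x[i] = nx;
      }
    } else {
      for (int i = 0; i < N; ++i) {
        double nx = x[i] + dt * (-x[i] + hid[i]) / tau_m;
        double nh = hid[i] + dt * (-hid[i] + rec[i]) / tau_h;
        if (sigma_eta > 0.0) nh += noise_sd / tau_h * norm_rand();
        x[i] = nx;
        hid[i] = nh;
      }
    }
    if (!x.is_finite())
      return List::create(_["error"] = true, _["step"] = s, _["time"] = s * dt);
    if (s % store_every == 0 && si < nstore) {
      X.col(si) = x;
      H.col(si) = hid;
      ++si;
    }
  }
  return List::create(_["error"] = false, _["x"] = X, _["hidden"] = H);
}

// Euler integration of independent two-variable single units, one per column of
// the drive matrix xi (the coloured DMFT noise, mean and any white component
// already folded in). Returns the current x at every step.
// [[Rcpp::export]]
arma::mat cpp_sim_unit(int mech, double tau_m, double tau_h, double g_w,
                       double gamma, const arma::mat& xi, double dt,
                       const arma::vec& x0, const arma::vec& hid0) {
  const int nsteps = xi.n_rows, trials = xi.n_cols;
  arma::mat X(nsteps, trials);
  for (int tr = 0; tr < trials; ++tr) {
    double x = x0[tr], h = hid0[tr];
    for (int s = 0; s < nsteps; ++s) {
      if (mech == 0) {
        double nx = x + dt * (-x - g_w * h + xi(s, tr)) / tau_m;
        h += dt * (-h + x - gamma) / tau_h;
        x = nx;
      } else {
        double nx = x + dt * (-x + h) / tau_m;
        h += dt * (-h + xi(s, tr)) / tau_h;
        x = nx;
      }
      X(s, tr) = x;
    }
  }
  return X;
}
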