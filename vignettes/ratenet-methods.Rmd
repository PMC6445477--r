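---
title: "Adaptation, synaptic filtering and the timescales of recurrent network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptation, synaptic filtering and the timescales of recurrent network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(ratenet)
```

## The models

`ratenet` analyses recurrent networks of \(N\) excitatory and inhibitory rate
units in which every unit carries, besides its input current \(x_i\), one
hidden slow variable. Two mechanisms are contrasted:

* **Adaptation** — a hidden variable \(w_i\) low-pass filters the linearised
  rate with time constant \(\tau_w\) and feeds back negatively into the
  current with coupling \(g_w\):
  \[
  \tau_m \dot x_i = -x_i - g_w w_i + \textstyle\sum_j J_{ij}\,\phi(x_j),
  \qquad
  \tau_w \dot w_i = -w_i + x_i - \gamma .
  \]
* **Synaptic filtering** — the summed synaptic input is low-pass filtered
  with time constant \(\tau_s\) before it drives the current:
  \[
  \tau_m \dot x_i = -x_i + s_i, \qquad
  \tau_s \dot s_i = -s_i + \textstyle\sum_j J_{ij}\,\phi(x_j).
  \]

Rates follow the bounded threshold-linear transfer
\(\phi(x) = \min([x-\gamma]^+, \phi_{max})\) (defaults \(\gamma=-0.5\),
\(\phi_{max}=2\)); time is measured in units of the membrane time constant
\(\tau_m\), which is nevertheless kept as an explicit parameter. The
adaptation variable low-passes the *linearised* rate \(x-\gamma\); this is
the model all the analytic theory refers to (the fully nonlinear variant is
available in the simulator behind `nonlinear_adaptation = TRUE` but is
deliberately excluded from the theory and the validation suite).

Connectivity is sparse, random and **constant in-degree**: every unit
receives exactly \(C_E\) excitatory synapses of weight \(+J\) and \(C_I\)
inhibitory synapses of weight \(-gJ\), drawn uniformly without replacement
from single-signed (Dale) pools. Defaults mirror the study conditions:
\(N=3000\), \(C_E=80\), \(C_I=20\), \(g=4.1\). Two ensemble scalars organise
everything:

* the common row sum \(J_{\mathrm{eff}} = J(C_E - gC_I)\) — the outlier
  eigenvalue, controlling the homogeneous (population-averaged) mode;
* the bulk radius \(J_{cs} = J\sqrt{C_E + g^2 C_I}\) — the radius of the
  eigenvalue disk, controlling the heterogeneous modes.

Because the excitatory pool fraction is not pinned down by the in-degrees,
the generator uses \(N_E = \mathrm{round}(N C_E / C)\), which makes the
expected out-degree uniform across units. Self-connections are excluded by
default but can be allowed (`allow_self`), since fixed in-degree ensembles
are conventionally defined either way.

## Single units and the population-averaged mode

Each single unit is a 2-D linear system; its impulse response is a sum of
two exponential modes obtained exactly from the propagator
(`synaptic_filter()`, `adaptive_filter()`). The degenerate case
\(\tau_s=\tau_m\) is kept exact with a polynomial-in-\(t\) mode rather than
by perturbing rates. Three scalar summaries matter downstream: the filter
area (DC gain), the amplitude-weighted timescale
\(\tau_{corr} = \sum_k |a_k|\tau_k / \sum_k |a_k|\), and the white-noise
variance gain \(\int h^2\). The variance gain is normalised for inputs of
**unit spectral density**, \(\langle I(t)I(t')\rangle = \delta(t-t')\) — the
only normalisation under which the quantity is finite — and this convention
is used consistently by the stochastic simulators.

The key single-unit asymmetry: the synaptic filter has equal-amplitude
modes, so its timescale grows linearly with \(\tau_s\); the adaptive slow
mode has area tending to \(-g_w/(1+g_w)\) independent of \(\tau_w\), so its
timescale saturates.

Homogeneous perturbations reduce to a 2-D system for the population average
(`popavg_stability()`). Stability is read off the trace and determinant:
synaptic networks are stable iff \(J_{\mathrm{eff}} < 1\) (saddle-node at 1,
independent of \(\tau_s\)); adaptive networks iff
\(J_{\mathrm{eff}} < \min(1+g_w,\, 1+\tau_m/\tau_w)\), with a Hopf boundary
active when \(\tau_m/\tau_w < g_w\). Exactly at the critical coupling the
linear equilibrium degenerates (it runs off to infinity), so the report
classifies the linear-regime dynamics there and labels the point
`marginal`; boundary equalities are detected with a \(10^{-9}\) tolerance
rather than forced to a side. Beyond the bifurcation the valid equilibrium
is the saturated one, whose dynamics are the always-stable single-unit
dynamics — `fixed_point()` therefore returns *all* regime solutions with
their validity, not only the linear one.

## Heterogeneous stability

Linearising the full \(2N\)-dimensional system, every network eigenvalue
\(\lambda\) maps onto a connectivity eigenvalue through
\(\lambda_J = (1+\tau_m\lambda)(1+\tau_s\lambda)\) (synaptic) or
\(\lambda_J = 1 + \tau_m\lambda + g_w/(1+\tau_w\lambda)\) (adaptation).
Mapping the imaginary axis \(\lambda = i\omega\) forward gives the stability
boundary in the \(\lambda_J\) plane; the bulk disk of radius \(J_{cs}\)
first touches it at
\(R^* = \min_\omega |\lambda_J^{sb}(\omega)|\), and the minimiser
\(\omega^*\) is the frequency of the first unstable mode
(`critical_radius()`). For synaptic filtering
\(|\lambda_J^{sb}|^2 = (1+\tau_m^2\omega^2)(1+\tau_s^2\omega^2)\) is
minimised trivially at \(\omega=0\): \(R^*=1\) always — synaptic filtering
does not move the instability. Adaptation pushes \(R^*\) above 1 and can
turn the bifurcation into a finite-frequency (Hopf) one.

The adaptive boundary is evaluated from the exact forward mapping at
\(\lambda = i\omega\) rather than from a rationalised closed form whose
printed denominators lose a sign; the exact curve reproduces both real-axis
anchors, \(1+g_w\) at \(\omega=0\) and \(1+\tau_m/\tau_w\) at
\(\omega = \sqrt{g_w\tau_w/\tau_m - 1}/\tau_w\) (when \(g_w\tau_w>\tau_m\)).
Minimisation uses a dense logarithmic grid over
\([10^{-4}/\tau_{hid},\,10^{2}/\tau_m]\) plus local refinement, with
\(\omega^* = 0\) reported whenever the origin value is not beaten (the
boundary is smooth there), so zero-frequency results are exact rather than
grid-limited.

A curvature comparison of the boundary against the eigenvalue circle at
\(\omega = 0\) gives the closed-form classification: the bifurcation is
zero-frequency iff
\[
\tau_m/\tau_w \;>\; g_w + \sqrt{2\,g_w(g_w+1)} ,
\]
and a Hopf otherwise. Expanding the boundary near \(\omega=0\) gives
\(\epsilon_y^2 = ((r-g_w)^2/g_w)\,\delta\) against the circle's
\(\epsilon_y^2 = 2(1+g_w)\,\delta\) (with \(r=\tau_m/\tau_w\) and \(\delta\)
the displacement toward the origin), from which the condition follows; its
\(\tau_w \to \tau_m\) root is exactly \(\sqrt5 - 2\approx 0.236\), the
coupling above which only a Hopf bifurcation is possible
(`hopf_only_coupling()`). The package's test-suite cross-checks this
condition against brute-force minimisation of the boundary modulus on both
sides of the threshold.

`full_jacobian_spectrum()` assembles the actual \(2N\times 2N\) Jacobian of
a sampled matrix and verifies that every computed eigenvalue maps back onto
the sampled connectivity spectrum — the structural identity behind the
whole reduction.

## The mean-field solver

Beyond the instability, the deterministic recurrent input to a unit is
replaced by an independent Gaussian process \(\xi\) with moments determined
self-consistently: mean \(J_{\mathrm{eff}}\langle\phi\rangle\) and
autocovariance \(J_{cs}^2 (C(\tau) - \langle\phi\rangle^2)\), plus
\(\sigma_\eta^2/2\,\delta(\tau)\) when intrinsic white noise is present.
`dmft_solve()` iterates: synthesize \(\xi\), integrate the reduced
two-variable unit over many trials, re-estimate
\(\langle\phi\rangle, C(\tau)\), and partially update the noise moments with
damping \(\alpha = 0.6\). Convergence requires the sup-norm change of both
moments to stay below a *relative* tolerance (8% of the lag-0
autocovariance — the level the default trial budget resolves — with an
absolute floor of \(3\times10^{-4}\) so the subcritical collapse onto
\(\Delta \equiv 0\) also terminates) for three consecutive iterations.

Numerical choices that matter:

* **Noise synthesis.** The coloured drive is generated in the Fourier
  domain with amplitude \(\sqrt{nS_k}\) — the square root of the circulant
  spectral density — and i.i.d. uniform phases. The square root is
  essential: amplitudes proportional to the density itself would give the
  process the squared autocorrelation, and a unit test locks this in.
  Negative spectral values (estimation noise in the target) are clipped and
  the clipped fraction recorded.
* **Static (frozen) component.** Because \(\phi\) is not odd, fluctuating
  states generically carry a non-decaying part of \(C(\tau)\): quenched
  across-unit heterogeneity of time-averaged rates. The solver carries this
  explicitly as a static variance of the drive, realised as per-trial
  constant offsets stratified over Gaussian quantiles. Its self-consistent
  update is estimated from the covariance of mean rates across trial
  *pairs* that share an offset but receive independent coloured noise —
  slow-but-decaying power cannot masquerade as frozen power in that
  estimator, whereas a lag-window plateau (also available via
  `static_method = "window_plateau"`) can. The static map is near-critical,
  so it is tracked undamped.
* **White-noise start.** The iteration starts from white noise whose
  *filtered* current variance is of order \(J_{cs}^2\)
  (`init_var = J_cs^2\,2(\tau_m+\tau_{hid})/dt`): white noise of order-one
  per-step variance would be annihilated by the low-pass filters and start
  the iteration deep in the trivial basin.
* **Moments.** \(\langle\phi\rangle\) and \(C(\tau)\) have dual routes:
  simulation averages, and Gaussian closures evaluated by quadrature
  (`gaussian_rate_mean()`, `gaussian_rate_autocorr()`). The transfer
  function is piecewise linear, so the quadrature splits the integral at
  the two corners and uses Gauss–Legendre panels — this is what lets the
  closed-form and quadrature routes agree to \(10^{-8}\) instead of the
  \(10^{-4}\) a Hermite rule achieves on a kinked integrand. At
  convergence the two routes agree within estimator noise, which is the
  self-consistency audit in the test-suite.

Default problem sizes (chosen once as a scale at which the estimators are
comfortably converged for the parameter ranges exercised here): 48 trials
per iteration and a final moment pass at 96, trial length
\(T = 20\,\tau_{slow} + \max(300\,\tau_m, 50\,\tau_{hid})\), step
\(dt = 0.05\,\min(\tau_m,\tau_{hid})\), lags up to
\(\min(15\,\tau_{hid}, (T-\mathrm{burn})/4)\).

## Timescale estimators

For linear systems the timescale is the amplitude-weighted mode timescale
above. For fluctuating regimes `envelope_timescale()` implements the
envelope width: \(\tau_{corr}\) is twice the lag at which the envelope of
the autocorrelation first reaches \(e^{-1/2}\) of its lag-0 value, with
linear interpolation between grid points and the plateau (mean of the last
10% of lags) removed first as the baseline.

The envelope itself deserves a note. The plain modulus of the analytic
signal is *not* the identity on monotone autocorrelations — the Hilbert
conjugate of \(e^{-|\tau|}\) is of order 0.4 near \(\tau = 0.5\) — so the
textbook construction would overestimate the width of non-oscillatory
autocorrelations by tens of percent and could not satisfy the calibration
identities (exponential \(\to\) its decay constant, Gaussian \(\to
2\sigma\)). The package therefore demodulates coherently: the analytic
signal \(z(\tau)\) of the evenly extended autocorrelation is rotated at the
dominant spectral frequency \(\omega_0\),
\(E(\tau) = \mathrm{Re}\,[z(\tau)e^{-i\omega_0\tau}]\). For monotone
autocorrelations \(\omega_0 = 0\) and the envelope is the function itself,
giving the calibration identities exactly; for damped oscillations the
rotation tracks the amplitude across zero crossings as the usual Hilbert
envelope does. When the envelope never reaches the threshold inside the
grid the estimator returns a failure flag instead of extrapolating.

```{r envelope, eval = FALSE}
lags <- seq(0, 100, 0.1)
envelope_timescale(exp(-lags / 10) * cos(2 * pi * lags / 5), lags)$tau_corr
#> ~ 10
```

## What the validation does and does not show

The synthetic networks generated by `build_connectivity()` *are* the model
class the theory addresses, so the suite validates internal consistency at
the study conditions (Dale-constrained constant in-degree, \(g = 4.1\),
four-to-one E/I in-degree), not agreement with biological data. Two
finite-size caveats surfaced repeatedly during development and are worth
recording:

* **Finite-density radius deficit.** At in-degree-to-size ratios \(C/N\)
  around 0.1 the realised bulk radius falls short of
  \(J\sqrt{C_E+g^2C_I}\) by roughly \(\sqrt{1 - C_E/N_E}\), visibly
  weakening fluctuations relative to the mean-field prediction. Comparisons
  between simulation and mean field are therefore run at the study's
  sparseness \(C/N \approx 1/30\), scaled down in \(N\).
* **Realisation scatter and slow edge modes.** At \(N = 1000\) the
  near-cancellation of excitatory and inhibitory column mass makes
  population-mean quantities vary by \(\pm 0.2\) current units across
  matrices, and eigenvalues near the critical circle produce
  realisation-specific slow autocorrelation tails with relaxation times of
  order \((\tau_s+\tau_m)/(R_{\mathrm{eff}}-1)\). The ensemble-mean
  autocorrelation of scaled-down networks consequently carries more
  mid-lag power than the \(N\to\infty\) mean field; the lag-0 amplitude and
  the short-lag shape agree at the few-percent level, but a uniform 10%
  sup-norm band over all lags is not attainable at \(N=1000\), and the
  corresponding check in the test-suite documents this as an expected
  failure rather than relaxing its bound.

Trend checks (timescale versus \(\tau_s\) or \(\tau_w\); variance versus
noise level and time constants) are asserted at parameter points where the
mechanism under test dominates estimator noise: the synaptic
variance-reduction trend, which acts on the *noise* pathway, is asserted at
\(\sigma_\eta = 0.5\), while the adaptation variance trends are visible
already at \(\sigma_\eta = 0.15\); strong-noise flattening of the
timescale is probed at \(\sigma_\eta = 1.5\). The adaptive
timescale-saturation law is asserted at the scale the solver resolves: the
curve rises steeply below \(\tau_w \approx 5\) and its late increments
(a few percent per unit \(\tau_w\)) lie below the per-point noise of
roughly \(\pm0.3\) even with multi-seed averaging, so the test checks the
steep initial rise, that all later points exceed the first, and that the
late mean slope is a small non-negative fraction of the initial one —
rather than strict per-increment ordering, which would test noise.

## Known limitations

* The iterative mean-field scheme loses reliability close to bifurcations
  (slow critical modes) and for very large hidden time constants (cost
  grows with \(\tau_{hid}/dt\)); non-convergence is reported with the full
  residual history, never silently.
* The analytic theory covers the linearised adaptation model; the
  nonlinear adaptation variant is simulation-only.
* Finite-size corrections to the circular law, structured (low-rank)
  connectivity and delay couplings are out of scope.
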