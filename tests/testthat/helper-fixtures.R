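# shared parameter sets and small sampled networks used across tests

p_adapt <- function(g_w = 0.5, tau_w = 5, tau_m = 1)
  unit_params("adaptation", tau_m = tau_m, g_w = g_w, tau_w = tau_w)

p_syn <- function(tau_s = 5, tau_m = 1)
  unit_params("synaptic", tau_m = tau_m, tau_s = tau_s)

# small sparse network with Table-1-style E/I composition (C_E : C_I = 4 : 1,
# g = 4.1) at a given bulk radius
small_net <- function(N = 200, radius = 0.8, seed = 11, C_E = 16, C_I = 4)
  build_connectivity(connectivity_spec(N = N, C_E = C_E, C_I = C_I,
                                       radius = radius, g = 4.1, seed = seed))

# brute-force reference: h(t) entries from the matrix exponential through
# eigendecomposition of a 2x2 system (independent of the filter code paths)
expm2 <- function(A, t) {
  e <- eigen(A)
  V <- e$vectors
  Re(V %*% diag(exp(e$values * t)) %*% solve(V))
}
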