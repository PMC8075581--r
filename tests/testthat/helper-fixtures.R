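# Small fixture builders shared across test files.

# tiny network: NE Pyr tiling an n^3 grid, NI PV interneurons
tiny_network <- function(n_per_dim = 2, NI = 2, seed = 42,
                         NE = n_per_dim^3) {
  # tiny row counts occasionally draw empty rows, which ei_network
  # resamples with a warning by design; silence it here
  suppressWarnings(
    ei_network(network_params(NE = NE, NI = NI, n_per_dim = n_per_dim),
               seed = seed))
}

# a hand-made ei_state with given activations
state_of <- function(hE, hI) ei_state(hE, hI)

# truncated homeostatic objective used as the finite-difference oracle for
# the gradient rules: activations respond only through the direct synaptic
# term (recurrent higher-order interactions removed), rates at baseline.
trunc_objective_EI <- function(W_EI_new, W_EI_old, hE, rI, rho0) {
  hE_new <- hE - drop((W_EI_new - W_EI_old) %*% rI)
  0.5 * sum((hE_new - rho0)^2)
}

trunc_objective_IE <- function(W_IE_new, W_IE_old, hE, hI, W_EI, rE, rho0) {
  hI_new <- hI + drop((W_IE_new - W_IE_old) %*% rE)
  rI_new <- pmax(hI_new, 0)
  hE_new <- hE - drop(W_EI %*% (rI_new - pmax(hI, 0)))
  0.5 * sum((hE_new - rho0)^2)
}

# central finite difference of f over each entry of W
fd_matrix <- function(f, W, eps = 1e-6) {
  G <- W * 0
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      Wp <- W; Wp[i, j] <- W[i, j] + eps
      Wm <- W; Wm[i, j] <- W[i, j] - eps
      G[i, j] <- (f(Wp) - f(Wm)) / (2 * eps)
    }
  }
  G
}

# scalar reference Adam (independent of the package implementation)
ref_adam <- function(grads, eta, beta1 = 0.9, beta2 = 0.999, eps = 1e-9) {
  m <- 0; v <- 0; u <- 0
  for (t in seq_along(grads)) {
    g <- grads[t]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    u <- u - eta * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
  }
  u
}
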