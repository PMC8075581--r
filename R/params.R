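#' Network parameters
#'
#' Collects the model constants: population sizes, rate time constants,
#' integration step, connection probabilities, per-neuron total incoming
#' weights for each projection, the log-weight spread of the random
#' initialisation, and the background input. Defaults are the full-scale
#' values used throughout.
#'
#' Projections are named `Y_X` for \eqn{Y \leftarrow X}; e.g. `J_IE` is the
#' total excitatory weight onto each interneuron
#' (\eqn{\sum_j W^{I \leftarrow E}_{ij}}).
#'
#' @param NE,NI Numbers of excitatory (Pyr) and inhibitory (PV) neurons.
#' @param tau_E,tau_I Rate time constants in ms.
#' @param dt Euler integration step in ms.
#' @param p Connection probability, applied to every projection.
#' @param J_EE,J_IE,J_EI,J_II Total incoming weight per neuron, by projection.
#' @param sigma_log Standard deviation of the natural log of the randomly
#'   initialised weights.
#' @param I_bg Constant background input (Hz) to all neurons.
#' @param n_per_dim Stimulus grid points per dimension; `NE` must equal
#'   `n_per_dim^3`.
#' @param kappa,max_rate Von Mises tuning width and peak input (Hz).
#' @return An object of class `"network_params"` (a validated list).
#' @export
network_params <- function(NE = 512, NI = 64, tau_E = 50, tau_I = 25, dt = 1,
                           p = 0.6, J_EE = 2, J_IE = 5, J_EI = 1, J_II = 1,
                           sigma_log = 0.65, I_bg = 5,
                           n_per_dim = 12, kappa = 1, max_rate = 50) {
  p_ <- list(NE = as.integer(NE), NI = as.integer(NI), tau_E = tau_E,
             tau_I = tau_I, dt = dt, p = p, J_EE = J_EE, J_IE = J_IE,
             J_EI = J_EI, J_II = J_II, sigma_log = sigma_log, I_bg = I_bg,
             n_per_dim = as.integer(n_per_dim), kappa = kappa,
             max_rate = max_rate)
  with(p_, {
    if (NE < 1 || NI < 1) stop("population sizes must be positive")
    if (tau_E <= 0 || tau_I <= 0 || dt <= 0) {
      stop("time constants and dt must be strictly positive")
    }
    if (dt >= min(tau_E, tau_I)) stop("'dt' must be smaller than both time constants")
    if (p <= 0 || p > 1) stop("'p' must lie in (0, 1]")
    if (any(c(J_EE, J_IE, J_EI, J_II) <= 0)) stop("J totals must be positive")
    if (sigma_log < 0) stop("'sigma_log' must be >= 0")
  })
  structure(p_, class = "network_params")
}
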