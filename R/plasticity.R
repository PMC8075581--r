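#' Plasticity configuration
#'
#' Selects the rule variant and collects learning parameters for the two
#' plastic projections: the PV output synapses (`EI`, inhibitory
#' PV-to-Pyr) and the PV input synapses (`IE`, excitatory Pyr-to-PV).
#' Both rules descend a single homeostatic objective, the mean squared
#' deviation of the Pyr activations from the target rate `rho0` across
#' stimuli.
#'
#' The `local` variant uses the biologically local approximations (the
#' input rule reads the interneuron's own recurrent excitatory current
#' against the target `I0 = J_IE * rho0`); the `gradient` variant uses the
#' steady-state first-order gradient, in which the input rule's error term
#' is propagated through the transposed output weights, and updates are
#' applied with Adam.
#'
#' @param rule `"local"` or `"gradient"`.
#' @param ko Knock-out mask: `"none"`, `"output"` (freeze `EI`) or
#'   `"input"` (freeze `IE`, including its row normalisation).
#' @param eta Learning rate; defaults to `1e-5` for the local rules and
#'   `1e-3` for the gradient rules.
#' @param rho0 Homeostatic Pyr target rate (Hz).
#' @param delta_EI,delta_IE Weight decay rates for the two projections.
#' @param beta1,beta2,epsilon Adam parameters (gradient variant).
#' @param reparam Sign-constraint reparameterisation. `"exp"` (default):
#'   weights are `exp` of an unconstrained parameter and the raw update is
#'   chain-ruled onto it, `w <- w * exp(eta * raw * w)`, so positivity is
#'   exact and weight changes are multiplicative. `"eg"` (exponentiated
#'   gradient): the raw update drives the log-weight directly, `w <- w *
#'   exp(eta * raw)`, which removes the extra factor `w` that makes large
#'   weights move disproportionately faster under `"exp"`. `"clip"`:
#'   additive updates clamped at zero.
#' @param normalise Multiplicatively rescale each PV row of the input
#'   matrix to its total `J_IE` after every update (applied in both rule
#'   variants).
#' @return An object of class `"plasticity_config"`.
#' @export
plasticity_config <- function(rule = c("local", "gradient"),
                              ko = c("none", "output", "input"),
                              eta = NULL, rho0 = 1,
                              delta_EI = 0.1, delta_IE = 0.1,
                              beta1 = 0.9, beta2 = 0.999, epsilon = 1e-9,
                              reparam = c("exp", "eg", "clip"),
                              normalise = TRUE) {
  rule <- match.arg(rule)
  ko <- match.arg(ko)
  reparam <- match.arg(reparam)
  if (is.null(eta)) eta <- if (rule == "local") 1e-5 else 1e-3
  if (rho0 <= 0) stop("'rho0' must be positive")
  if (eta <= 0) stop("'eta' must be positive")
  structure(list(rule = rule, ko = ko, eta = eta, rho0 = rho0,
                 delta_EI = delta_EI, delta_IE = delta_IE,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 reparam = reparam, normalise = normalise),
            class = "plasticity_config")
}

#' Homeostatic update of the PV output synapses
#'
#' Raw (pre-learning-rate) update of the inhibitory PV-to-Pyr weights:
#' \deqn{\Delta W^{E\leftarrow I}_{ji} = (h^E_j - \rho_0)\, r^I_i - \delta_{EI} W_{ji},}
#' a Hebbian change in proportion to presynaptic interneuron activity and
#' the signed deviation of the postsynaptic Pyr activation from the target.
#' Raising an inhibitory weight lowers the Pyr activation, so a positive
#' deviation strengthens inhibition. Applied on the connectivity mask only.
#' This is also the (truncated) gradient form for the output projection.
#'
#' @param state Steady-state [ei_state()] for the current stimulus.
#' @param W Weight list.
#' @param mask Logical connectivity mask for `EI`.
#' @param cfg A [plasticity_config()].
#' @return Raw update matrix for `W$EI` (NE by NI).
#' @export
local_output_update <- function(state, W, mask, cfg) {
  raw <- outer(state$hE - cfg$rho0, state$rI)
  raw[!mask] <- 0
  raw - cfg$delta_EI * W$EI
}

#' Homeostatic update of the PV input synapses (local rule)
#'
#' Raw update of the excitatory Pyr-to-PV weights:
#' \deqn{\Delta W^{I\leftarrow E}_{ij} = \Big[\sum_k W^{I\leftarrow E}_{ik}(r^E_k - \rho_0)\Big] r^E_j - \delta_{IE} W_{ij}.}
#' With row totals normalised to `J_IE`, the bracket equals the deviation
#' of the interneuron's recurrent excitatory current from the target
#' `I0 = J_IE * rho0`, making the rule local to the postsynaptic cell.
#'
#' @inheritParams local_output_update
#' @param mask Logical connectivity mask for `IE`.
#' @return Raw update matrix for `W$IE` (NI by NE).
#' @export
local_input_update <- function(state, W, mask, cfg) {
  err <- drop(W$IE %*% (state$rE - cfg$rho0))
  raw <- outer(err, state$rE)
  raw[!mask] <- 0
  raw - cfg$delta_IE * W$IE
}

#' Gradient-based updates of both plastic projections
#'
#' Steady-state first-order gradient of the homeostatic objective, with
#' backpropagation through time collapsed at the fixed point and
#' higher-order recurrent interactions neglected. The output update is
#' identical in form to [local_output_update()]. The input update replaces
#' the local current-deviation proxy by the error propagated through the
#' transposed output weights, gated by the interneuron rectifier:
#' \deqn{\Delta W^{I\leftarrow E}_{ij} = \Big[\sum_k W^{E\leftarrow I}_{ki}(h^E_k - \rho_0)\Big] g_i\, r^E_j - \delta_{IE} W_{ij},}
#' with \eqn{g_i = 1} if \eqn{h^I_i > 0} and 0 otherwise.
#'
#' @inheritParams local_output_update
#' @param masks List of logical masks (`EI`, `IE`).
#' @return List with raw update matrices `EI` and `IE`.
#' @export
gradient_updates <- function(state, W, masks, cfg) {
  out <- local_output_update(state, W, masks$EI, cfg)
  err <- drop(crossprod(W$EI, state$hE - cfg$rho0)) * (state$hI > 0)
  raw <- outer(err, state$rE)
  raw[!masks$IE] <- 0
  list(EI = out, IE = raw - cfg$delta_IE * W$IE)
}

#' Adam optimiser state
#'
#' First- and second-moment accumulators for one plastic matrix, plus the
#' step counter.
#'
#' @param dim Dimensions of the matrix being optimised.
#' @return An object of class `"adam_state"`.
#' @export
adam_state <- function(dim) {
  structure(list(m = matrix(0, dim[1], dim[2]),
                 v = matrix(0, dim[1], dim[2]), t = 0L),
            class = "adam_state")
}

# One Adam step. g is the gradient of the quantity being *minimised*;
# returns list(delta = parameter increment, state = updated accumulators).
.adam_step <- function(state, g, eta, beta1, beta2, epsilon) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(delta = -eta * mhat / (sqrt(vhat) + epsilon), state = state)
}

#' Apply a raw plasticity update to a weight matrix
#'
#' Converts a raw update (an ascent direction in weight space, decay
#' included) into an actual weight change under the configured
#' sign-constraint reparameterisation, optionally through Adam.
#'
#' Weights are `w = exp(u)` under both multiplicative variants. With
#' `exp` the parameter receives the chain-ruled gradient `eta * raw * w`,
#' i.e. `w <- w * exp(eta * raw * w)`; with `eg` (exponentiated gradient)
#' the raw update moves the log-weight directly, `w <- w * exp(eta *
#' raw)`. Under `clip`, `w <- max(w + eta * raw, 0)`. Masked-out entries
#' never change. With an [adam_state()] supplied, the parameter step is
#' produced by Adam from the (negated) parameter gradient instead of
#' plain scaling.
#'
#' @param W Weight matrix (magnitudes, nonnegative).
#' @param raw Raw update matrix, same shape.
#' @param eta Learning rate.
#' @param cfg A [plasticity_config()] (for `reparam` and Adam constants).
#' @param optim Optional [adam_state()].
#' @return List with `W` (updated matrix) and `optim` (possibly updated).
#' @export
apply_update <- function(W, raw, eta, cfg, optim = NULL) {
  if (any(!is.finite(raw))) stop("non-finite plasticity update")
  if (cfg$reparam %in% c("exp", "eg")) {
    # parameter-space (log-weight) ascent direction
    g <- if (cfg$reparam == "eg") raw else raw * W
    if (is.null(optim)) {
      W <- W * exp(eta * g)
    } else {
      st <- .adam_step(optim, -g, eta, cfg$beta1, cfg$beta2, cfg$epsilon)
      W <- W * exp(st$delta)
      optim <- st$state
    }
  } else {
    if (is.null(optim)) {
      W <- pmax(W + eta * raw, 0)
    } else {
      st <- .adam_step(optim, -raw, eta, cfg$beta1, cfg$beta2, cfg$epsilon)
      W <- pmax(W + st$delta * (W > 0), 0)
      optim <- st$state
    }
  }
  list(W = W, optim = optim)
}

#' Multiplicative row normalisation of the PV input weights
#'
#' Rescales each interneuron's incoming excitatory weights so that their
#' sum equals `J_IE`. Called after every update of the input matrix.
#'
#' @param W_IE Input weight matrix (NI by NE).
#' @param J_IE Target row total.
#' @return The rescaled matrix.
#' @export
normalise_input_rows <- function(W_IE, J_IE) {
  rs <- rowSums(W_IE)
  if (any(rs <= 0)) stop("row normalisation failed: a PV row has zero total weight")
  W_IE * (J_IE / rs)
}
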