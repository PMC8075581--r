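#' @export
print.ei_network <- function(x, ...) {
  p <- x$params
  cat(sprintf("E/I rate network: %d Pyr, %d PV neurons\n", p$NE, p$NI))
  cat(sprintf("stimulus grid: %d x %d x %d (%d stimuli), von Mises kappa = %g, peak %g Hz\n",
              p$n_per_dim, p$n_per_dim, p$n_per_dim, x$grid$n_stimuli,
              p$kappa, p$max_rate))
  cat(sprintf("connection density %.2f; row totals J_EE=%g J_IE=%g J_EI=%g J_II=%g\n",
              mean(x$masks$EE[row(x$masks$EE) != col(x$masks$EE)]),
              p$J_EE, p$J_IE, p$J_EI, p$J_II))
  invisible(x)
}

#' @export
print.ei_fit <- function(x, ...) {
  cat(sprintf("trained E/I network (%s rule%s), %d trials x %d stimuli\n",
              x$config$rule,
              if (x$config$ko != "none") paste0(", ", x$config$ko, " KO") else "",
              x$trials, x$network$grid$n_stimuli))
  md <- x$history$mean_dev
  cat(sprintf("mean |hE - rho0|: %.3f (first trial) -> %.3f (last trial)\n",
              md[1], md[length(md)]))
  invisible(x)
}

#' Summarise a trained network
#'
#' Computes the steady-state response tensor with the trained weights and
#' reports homeostatic convergence (median Pyr activation across neurons
#' and stimuli against the target) and the stimulus selectivity of both
#' populations, before and after learning.
#'
#' @param object An `ei_fit`.
#' @param responses Optional precomputed `ei_responses` for the trained
#'   weights (saves recomputation).
#' @param responses_before Optional `ei_responses` for the initial weights.
#' @param ... Unused.
#' @return An object of class `"summary.ei_fit"`.
#' @export
summary.ei_fit <- function(object, responses = NULL,
                           responses_before = NULL, ...) {
  net <- object$network
  NE <- net$params$NE
  if (is.null(responses)) responses <- response_tensor(net, W = object$W)
  if (is.null(responses_before)) responses_before <- response_tensor(net)
  sel <- function(resp) {
    apply(resp$rates, 1L, stimulus_selectivity)
  }
  s_after <- sel(responses); s_before <- sel(responses_before)
  out <- list(
    rho0 = object$config$rho0,
    median_hE = stats::median(responses$activations[seq_len(NE), ]),
    mean_dev_last = utils::tail(object$history$mean_dev, 1L),
    selectivity = data.frame(
      population = c("Pyr", "PV"),
      before = c(stats::median(s_before[seq_len(NE)]),
                 stats::median(s_before[-seq_len(NE)])),
      after = c(stats::median(s_after[seq_len(NE)]),
                stats::median(s_after[-seq_len(NE)]))),
    config = object$config, trials = object$trials)
  class(out) <- "summary.ei_fit"
  out
}

#' @export
print.summary.ei_fit <- function(x, ...) {
  cat(sprintf("homeostatic target rho0 = %g Hz; median steady-state Pyr activation = %.3f Hz\n",
              x$rho0, x$median_hE))
  cat(sprintf("final mean |hE - rho0| = %.3f Hz\n", x$mean_dev_last))
  cat("median stimulus selectivity (skewness):\n")
  print(x$selectivity, row.names = FALSE)
  invisible(x)
}

#' Extract weight matrices
#'
#' @param object An `ei_fit` or `ei_network`.
#' @param ... Unused.
#' @return Named list of the four weight matrices (`EE`, `EI`, `IE`, `II`).
#' @export
coef.ei_fit <- function(object, ...) object$W

#' @rdname coef.ei_fit
#' @export
coef.ei_network <- function(object, ...) object$W

#' Steady-state responses of a trained network
#'
#' @param object An `ei_fit`.
#' @param stimuli Optional stimulus matrix (rows are stimuli in
#'   \eqn{[-\pi,\pi)^3}); defaults to the full grid.
#' @param ... Passed to [response_tensor()].
#' @return An `ei_responses`.
#' @export
predict.ei_fit <- function(object, stimuli = NULL, ...) {
  response_tensor(object$network, W = object$W, stimuli = stimuli, ...)
}

#' Homeostatic residuals
#'
#' Deviations of the steady-state Pyr activations from the homeostatic
#' target, per neuron and stimulus: the quantity the plasticity rules
#' drive to zero.
#'
#' @param object An `ei_fit`.
#' @param responses Optional precomputed `ei_responses`.
#' @param ... Unused.
#' @return NE by n_stimuli matrix of `hE - rho0`.
#' @export
residuals.ei_fit <- function(object, responses = NULL, ...) {
  if (is.null(responses)) {
    responses <- response_tensor(object$network, W = object$W)
  }
  responses$activations[seq_len(object$network$params$NE), , drop = FALSE] -
    object$config$rho0
}

#' Simulate the rate dynamics over time
#'
#' Integrates the Wilson-Cowan dynamics for a fixed stimulus from a given
#' initial state, returning the activation trajectories (no plasticity).
#'
#' @param object An `ei_fit` or `ei_network`.
#' @param nsim Number of Euler steps.
#' @param seed Unused (the dynamics are deterministic); kept for the
#'   generic's signature.
#' @param stimulus Index into the stimulus grid, or a 3-vector.
#' @param state Optional initial [ei_state()] (default zero activations).
#' @param ... Unused.
#' @return List with matrices `hE`, `hI` (neurons by time steps).
#' @export
simulate.ei_fit <- function(object, nsim = 1000, seed = NULL, stimulus = 1L,
                            state = NULL, ...) {
  network <- if (inherits(object, "ei_fit")) object$network else object
  W <- if (inherits(object, "ei_fit")) object$W else object$W
  params <- network$params
  input <- if (length(stimulus) == 3L) {
    drop(input_matrix(network$tuning, matrix(stimulus, 1L)))
  } else {
    network$inputs[, stimulus]
  }
  if (is.null(state)) state <- ei_state(rep(0, params$NE), rep(0, params$NI))
  hE <- matrix(0, params$NE, nsim)
  hI <- matrix(0, params$NI, nsim)
  for (t in seq_len(nsim)) {
    state <- euler_step(state, W, input, params)
    hE[, t] <- state$hE
    hI[, t] <- state$hI
  }
  list(hE = hE, hI = hI)
}

#' @export
simulate.ei_network <- simulate.ei_fit

#' Diagnostic plots for a trained network
#'
#' Draws (1) the per-trial mean deviation of Pyr activations from the
#' homeostatic target, (2) the feedback-alignment angle between local and
#' gradient input updates over presentations, and, when a synapse sample
#' is supplied, (3) scatter plots of input/output weights against
#' response similarity.
#'
#' @param x An `ei_fit`.
#' @param sample Optional data.frame from [sample_reciprocal_pairs()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ei_fit <- function(x, sample = NULL, ...) {
  n_panels <- 2L + 2L * !is.null(sample)
  op <- graphics::par(mfrow = c(1L, n_panels))
  on.exit(graphics::par(op))
  graphics::plot(x$history$mean_dev, type = "l", xlab = "trial",
                 ylab = "mean |hE - rho0| (Hz)",
                 main = "homeostatic convergence", ...)
  ok <- is.finite(x$history$angle)
  graphics::plot(x$history$angle_at[ok], x$history$angle[ok] * 180 / pi,
                 type = "l", xlab = "presentation", ylab = "angle (deg)",
                 main = "feedback alignment", ...)
  graphics::abline(h = 90, lty = 2)
  if (!is.null(sample)) {
    graphics::plot(sample$rs, sample$w_in, xlab = "response similarity",
                   ylab = "input weight (Pyr to PV)", main = "input synapses")
    graphics::plot(sample$rs, sample$w_out, xlab = "response similarity",
                   ylab = "output weight (PV to Pyr)", main = "output synapses")
  }
  invisible(x)
}
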