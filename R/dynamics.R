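#' Create a network state
#'
#' Holds the activations `hE`, `hI` (which may be negative) and the
#' rectified firing rates `rE = max(hE, 0)`, `rI = max(hI, 0)`.
#'
#' @param hE,hI Numeric activation vectors.
#' @return An object of class `"ei_state"`.
#' @export
ei_state <- function(hE, hI) {
  structure(list(hE = hE, hI = hI,
                 rE = pmax(hE, 0), rI = pmax(hI, 0)),
            class = "ei_state")
}

#' One Euler step of the Wilson-Cowan rate dynamics
#'
#' Advances the activations by one step of
#' \deqn{\tau_E \dot h^E = -h^E + W^{E\leftarrow E} r^E - W^{E\leftarrow I} r^I + I_{bg} + I(s)}
#' \deqn{\tau_I \dot h^I = -h^I + W^{I\leftarrow E} r^E - W^{I\leftarrow I} r^I + I_{bg}}
#' with rates re-rectified after the update. Weight matrices are magnitudes;
#' the inhibitory sign is applied here.
#'
#' @param state An [ei_state()].
#' @param W Weight list with elements `EE`, `EI`, `IE`, `II`.
#' @param input External input vector to the Pyr population (one stimulus).
#' @param params A [network_params()] (uses `tau_E`, `tau_I`, `dt`, `I_bg`).
#' @return The updated `ei_state`.
#' @export
euler_step <- function(state, W, input, params) {
  if (any(!is.finite(state$hE)) || any(!is.finite(state$hI))) {
    stop("numerical divergence: non-finite activations")
  }
  dE <- -state$hE + drop(W$EE %*% state$rE) - drop(W$EI %*% state$rI) +
    params$I_bg + input
  dI <- -state$hI + drop(W$IE %*% state$rE) - drop(W$II %*% state$rI) +
    params$I_bg
  ei_state(state$hE + (params$dt / params$tau_E) * dE,
           state$hI + (params$dt / params$tau_I) * dI)
}

# Combined signed weight matrix [[EE, -EI], [IE, -II]] for fixed-point solves.
.signed_matrix <- function(W) {
  rbind(cbind(W$EE, -W$EI), cbind(W$IE, -W$II))
}

# Attempt a direct fixed-point solve for a given active set.
# Solves (I - M diag(a)) h = cc; returns h or NULL if inconsistent/singular.
.fixed_point_solve <- function(M, cc, active) {
  n <- length(cc)
  A <- -M
  A[, !active] <- 0
  diag(A) <- diag(A) + 1
  h <- tryCatch(solve(A, cc), error = function(e) NULL)
  if (is.null(h)) return(NULL)
  if (!all((h > 0) == active)) return(NULL)
  h
}

#' Steady state of the rate dynamics for one stimulus
#'
#' Integrates the dynamics with [euler_step()] until the largest activation
#' change per step falls below `tol`. Because the rectified-linear dynamics
#' are piecewise linear, the solver also attempts an exact algebraic
#' fixed-point solve whenever the active set (the sign pattern of the
#' activations) has been stable for `solve_after` consecutive steps; the
#' solution is accepted only if its sign pattern is self-consistent. This
#' accelerates convergence without changing the fixed point.
#'
#' @param W Weight list (`EE`, `EI`, `IE`, `II`).
#' @param input External Pyr input vector for the stimulus.
#' @param params A [network_params()].
#' @param state Optional warm-start [ei_state()]; defaults to zero
#'   activations.
#' @param tol Convergence tolerance on the per-step activation change (Hz).
#' @param max_steps Maximum number of Euler steps before failing.
#' @param solve_after Number of steps of active-set stability before a
#'   direct solve is attempted (set to `Inf` to disable).
#' @param M Optional precomputed signed weight matrix (internal reuse).
#' @param on_cycle What to do when the dynamics settle into a bounded
#'   oscillation (a limit cycle) instead of a fixed point: `"error"`
#'   (default, the strict contract) or `"average"`, which returns the
#'   cycle-averaged activations and rates with attribute `cycle = TRUE`.
#'   Transient oscillatory weight configurations do arise during learning;
#'   averaging over the cycle is then the natural substrate for the
#'   homeostatic updates and for rate measurements.
#' @param cycle_after Simulated milliseconds without convergence before a
#'   bounded oscillation is declared a limit cycle (default 800 ms, about
#'   16 excitatory time constants; the running average then spans several
#'   oscillation periods).
#' @return An `ei_state` with attributes `steps` (Euler steps taken),
#'   `solved` (logical, whether the algebraic solve finished the job) and
#'   `cycle` (logical).
#' @export
steady_state <- function(W, input, params, state = NULL, tol = 1e-6,
                         max_steps = 1e5, solve_after = 50, M = NULL,
                         on_cycle = c("error", "average"),
                         cycle_after = 800) {
  on_cycle <- match.arg(on_cycle)
  NE <- length(input); NI <- nrow(W$IE)
  if (is.null(state)) state <- ei_state(rep(0, NE), rep(0, NI))
  if (is.null(M)) M <- .signed_matrix(W)
  cc <- c(params$I_bg + input, rep(params$I_bg, NI))
  dt_eff <- params$dt
  tau <- c(rep(params$tau_E, NE), rep(params$tau_I, NI))
  a <- dt_eff / tau
  h <- c(state$hE, state$hI)
  r <- pmax(h, 0)
  active_prev <- h > 0
  stable <- 0L
  step <- 0L
  havg <- h                # running averages, for oscillation fallback
  ravg <- r
  t_sim <- 0
  res_prev_chk <- Inf
  amax_chk <- max(abs(havg))
  accept <- function(h, step, solved, cycle = FALSE, r = NULL) {
    out <- ei_state(h[seq_len(NE)], h[NE + seq_len(NI)])
    if (!is.null(r)) {      # cycle-averaged rates (rectification is nonlinear)
      out$rE <- r[seq_len(NE)]
      out$rI <- r[NE + seq_len(NI)]
    }
    attr(out, "steps") <- step
    attr(out, "solved") <- solved
    attr(out, "cycle") <- cycle
    out
  }
  repeat {
    # try the exact solve once the active set looks settled
    if (stable >= solve_after) {
      hs <- .fixed_point_solve(M, cc, active_prev)
      if (!is.null(hs)) return(accept(hs, step, TRUE))
      stable <- -Inf  # solve failed for this active set; keep integrating
    }
    dh <- a * (drop(M %*% r) + (cc - h))
    h <- h + dh
    if (any(!is.finite(h))) {
      stop("numerical divergence during steady-state integration")
    }
    r <- pmax(h, 0)
    step <- step + 1L
    res <- max(abs(dh)) * params$dt / dt_eff
    if (res < tol) return(accept(h, step, FALSE))
    t_sim <- t_sim + dt_eff
    alpha <- 0.01 * dt_eff / params$dt
    havg <- (1 - alpha) * havg + alpha * h
    ravg <- (1 - alpha) * ravg + alpha * r
    active <- h > 0
    if (all(active == active_prev)) stable <- stable + 1L else stable <- 0L
    active_prev <- active
    # Forward Euler at the nominal dt can be linearly unstable for strongly
    # underdamped E-I modes although the continuous fixed point is stable.
    # Every 500 steps without progress: try the exact solve with the sign
    # pattern of the time-averaged state, then shrink the internal step.
    if (step %% 500L == 0L) {
      hs <- .fixed_point_solve(M, cc, havg > 0)
      if (is.null(hs)) hs <- .fixed_point_solve(M, cc, active)
      if (!is.null(hs)) return(accept(hs, step, TRUE))
      if (res >= 0.5 * res_prev_chk && dt_eff > params$dt / 16) {
        dt_eff <- dt_eff / 2
        a <- dt_eff / tau
      }
      res_prev_chk <- res
    }
    amax <- max(abs(h))
    if (amax > 1e6) {
      stop("numerical divergence during steady-state integration")
    }
    if (on_cycle == "average" && t_sim >= cycle_after) {
      # accept the running average only for a bounded, stationary
      # oscillation: the amplitude must not have grown since the last check
      if (amax <= 2 * amax_chk + 10) {
        return(accept(havg, step, FALSE, cycle = TRUE, r = ravg))
      }
    }
    if (step %% 500L == 0L) amax_chk <- amax
    if (step >= max_steps) {
      stop(sprintf(paste0("steady state not reached in %d steps ",
                          "(max residual %.3g, oscillating active set: %s)"),
                   max_steps, res, ifelse(stable < 5, "yes", "no")))
    }
  }
}

# Batched forward-Euler pre-integration of all stimuli at once (one
# matrix-matrix product per step); brings every column near its attractor
# so the per-stimulus solver finishes in a few steps.
.batch_presolve <- function(M, CC, params, NE, NI, steps = 1000L) {
  a <- c(rep(params$dt / params$tau_E, NE), rep(params$dt / params$tau_I, NI))
  H <- CC
  for (k in seq_len(steps)) {
    H2 <- H + a * (M %*% pmax(H, 0) + (CC - H))
    bad <- !is.finite(H2) | abs(H2) > 1e6
    if (any(bad)) H2[bad] <- H[bad]  # freeze diverging columns at last value
    H <- H2
  }
  H
}

#' Steady-state responses to a set of stimuli
#'
#' Computes the steady state for every stimulus of a grid (or an arbitrary
#' stimulus matrix). All stimuli are first integrated jointly for a few
#' hundred Euler steps (a single matrix product per step), then each
#' stimulus is finished individually by [steady_state()] from that warm
#' start. The fixed point does not depend on the initial condition when
#' the dynamics are stable, so warm starts only speed things up.
#'
#' @param network An `ei_network`, or a list with elements `W`, `params`,
#'   `tuning`.
#' @param W Optional weight list overriding `network$W` (e.g. trained
#'   weights).
#' @param stimuli Optional stimulus matrix (rows are stimuli); defaults to
#'   the network's full grid.
#' @param tol,max_steps,solve_after,on_cycle Passed to [steady_state()];
#'   limit cycles are averaged by default here, so that oscillatory
#'   stimuli yield their mean rates.
#' @return An object of class `"ei_responses"`: list with `rates` and
#'   `activations`, both `(NE + NI)` by `n_stimuli` matrices (Pyr rows
#'   first), plus `NE`, `NI`, and `n_cycles` (stimuli that oscillated).
#' @export
response_tensor <- function(network, W = NULL, stimuli = NULL, tol = 1e-6,
                            max_steps = 1e5, solve_after = 50,
                            on_cycle = "average") {
  params <- network$params
  if (is.null(W)) W <- network$W
  inputs <- if (is.null(stimuli)) {
    network$inputs
  } else {
    input_matrix(network$tuning, stimuli)
  }
  NS <- ncol(inputs)
  NE <- params$NE; NI <- params$NI
  M <- .signed_matrix(W)
  CC <- rbind(inputs + params$I_bg,
              matrix(params$I_bg, NI, NS))
  H0 <- .batch_presolve(M, CC, params, NE, NI)
  rates <- matrix(0, NE + NI, NS)
  acts <- matrix(0, NE + NI, NS)
  n_cycles <- 0L
  for (s in seq_len(NS)) {
    # after the joint pre-integration most columns are one exact solve
    # away from their fixed point
    hs <- .fixed_point_solve(M, CC[, s], H0[, s] > 0)
    if (!is.null(hs)) {
      acts[, s] <- hs
      rates[, s] <- pmax(hs, 0)
      next
    }
    state <- steady_state(W, inputs[, s], params,
                          state = ei_state(H0[seq_len(NE), s],
                                           H0[NE + seq_len(NI), s]),
                          tol = tol, max_steps = max_steps,
                          solve_after = min(solve_after, 10L),
                          M = M, on_cycle = on_cycle)
    n_cycles <- n_cycles + isTRUE(attr(state, "cycle"))
    acts[, s] <- c(state$hE, state$hI)
    rates[, s] <- c(state$rE, state$rI)
  }
  structure(list(rates = rates, activations = acts, NE = NE, NI = NI,
                 n_cycles = n_cycles),
            class = "ei_responses")
}
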