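#' Train the network with homeostatic interneuron plasticity
#'
#' Runs the training protocol: in every trial all grid stimuli are
#' presented once in a fresh random order; each presentation is held until
#' the rate dynamics reach steady state, and only then are the plastic
#' weights updated. After every update of the PV input matrix its rows are
#' renormalised to the total `J_IE`. Knock-out variants freeze one plastic
#' matrix entirely (see `ko` in [plasticity_config()]).
#'
#' The recorder captures the alignment angle between the local and the
#' gradient-based input update (their error-driven parts, excluding the
#' shared decay term) at every presentation during the first 4% of
#' training and every 100th presentation afterwards, plus weight snapshots
#' every `snapshot_every` trials and the per-trial mean absolute deviation
#' of the Pyr activations from the target.
#'
#' @param network An [ei_network()]; it is not modified.
#' @param config A [plasticity_config()].
#' @param trials Number of trials (full sweeps over the stimulus grid).
#' @param seed Integer seed for the per-trial stimulus permutations.
#' @param snapshot_every Trial interval between weight snapshots.
#' @param tol,max_steps Steady-state solver settings.
#' @param verbose Print a progress line every 10 trials.
#' @return An object of class `"ei_fit"`: list with `network` (the initial
#'   network), `W` (trained weights), `config`, `trials`, `seed`, and
#'   `history` (angle series with presentation indices, per-trial mean
#'   deviation, weight snapshots).
#' @seealso [run_knockout()], [perturb_influence()], [predict.ei_fit()],
#'   [residuals.ei_fit()]
#' @export
ei_train <- function(network, config = plasticity_config(), trials = 500,
                     seed = 1L, snapshot_every = 10L, tol = 1e-6,
                     max_steps = 1e5, verbose = FALSE) {
  stopifnot(inherits(network, "ei_network"),
            inherits(config, "plasticity_config"))
  if (trials < 1) stop("'trials' must be a positive count")
  params <- network$params
  W <- network$W
  masks <- network$masks
  NS <- network$grid$n_stimuli
  n_pres <- trials * NS
  angle_full_until <- ceiling(0.04 * n_pres)

  optim <- NULL
  if (config$rule == "gradient") {
    optim <- list(EI = adam_state(dim(W$EI)), IE = adam_state(dim(W$IE)))
  }

  angles <- numeric(0)
  angle_at <- integer(0)
  mean_dev <- numeric(trials)
  snapshots <- list()

  set.seed(as.integer(seed))
  state <- NULL
  pres <- 0L
  n_cycles <- 0L
  t_start <- proc.time()[["elapsed"]]
  for (trial in seq_len(trials)) {
    order_s <- sample.int(NS)
    dev_acc <- 0
    for (s in order_s) {
      pres <- pres + 1L
      state <- tryCatch(
        steady_state(W, network$inputs[, s], params, state = state,
                     tol = tol, max_steps = max_steps,
                     on_cycle = "average"),
        error = function(e) {
          stop(sprintf("trial %d, stimulus %d: %s", trial, s,
                       conditionMessage(e)))
        })
      n_cycles <- n_cycles + isTRUE(attr(state, "cycle"))
      dev_acc <- dev_acc + mean(abs(state$hE - config$rho0))

      # raw updates (decay included) under the active rule variant
      if (config$rule == "gradient") {
        upd <- gradient_updates(state, W, masks, config)
        raw_EI <- upd$EI
        raw_IE <- upd$IE
      } else {
        raw_EI <- local_output_update(state, W, masks$EI, config)
        raw_IE <- local_input_update(state, W, masks$IE, config)
      }

      # feedback-alignment angle between local and gradient input updates
      # (error-driven parts only; the decay term is common to both)
      if (pres <= angle_full_until || pres %% 100L == 0L) {
        errL <- drop(W$IE %*% (state$rE - config$rho0))
        errG <- drop(crossprod(W$EI, state$hE - config$rho0)) *
          (state$hI > 0)
        A <- outer(errL, state$rE)
        G <- outer(errG, state$rE)
        A[!masks$IE] <- 0
        G[!masks$IE] <- 0
        ang <- if (sum(A^2) == 0 || sum(G^2) == 0) NA_real_ else
          update_angle(G, A)
        angles <- c(angles, ang)
        angle_at <- c(angle_at, pres)
      }

      if (config$ko != "output") {
        st <- apply_update(W$EI, raw_EI, config$eta, config, optim$EI)
        W$EI <- st$W
        if (!is.null(optim)) optim$EI <- st$optim
      }
      if (config$ko != "input") {
        st <- apply_update(W$IE, raw_IE, config$eta, config, optim$IE)
        W$IE <- st$W
        if (!is.null(optim)) optim$IE <- st$optim
        if (config$normalise) W$IE <- normalise_input_rows(W$IE, params$J_IE)
      }
    }
    mean_dev[trial] <- dev_acc / NS
    if (trial == 1L || trial == trials || trial %% snapshot_every == 0L) {
      snapshots[[as.character(trial)]] <- list(EI = W$EI, IE = W$IE)
    }
    if (verbose && trial %% 10L == 0L) {
      message(sprintf("trial %d/%d  mean|hE - rho0| = %.4f  (%.1f s)",
                      trial, trials, mean_dev[trial],
                      proc.time()[["elapsed"]] - t_start))
    }
  }

  structure(list(network = network, W = W, config = config, trials = trials,
                 seed = as.integer(seed),
                 history = list(angle = angles, angle_at = angle_at,
                                mean_dev = mean_dev, snapshots = snapshots,
                                n_cycles = n_cycles)),
            class = "ei_fit")
}

#' Virtual knock-out experiment
#'
#' Re-runs [ei_train()] with plasticity disabled in one synapse class: the
#' named matrix (and, for the input matrix, its row normalisation) is
#' frozen bit-exactly at its initial value while the other rule operates
#' normally.
#'
#' @param network An [ei_network()].
#' @param variant `"output_ko"` (freeze PV-to-Pyr) or `"input_ko"`
#'   (freeze Pyr-to-PV).
#' @param config Base [plasticity_config()]; its `ko` field is overridden.
#' @param ... Passed to [ei_train()].
#' @return An `ei_fit`.
#' @export
run_knockout <- function(network, variant = c("output_ko", "input_ko"),
                         config = plasticity_config(), ...) {
  variant <- match.arg(variant)
  config$ko <- sub("_ko$", "", variant)
  ei_train(network, config, ...)
}
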