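#' Single-neuron perturbation experiment
#'
#' Transiently increases the afferent drive of one excitatory neuron at a
#' time by `delta_I` and measures the steady-state rate change this causes
#' in every other Pyr neuron, for each stimulus, with all plasticity
#' disabled. The influence of perturbed neuron i on neuron j is the rate
#' difference normalised by the perturbation magnitude, averaged over
#' stimuli.
#'
#' @param object An `ei_fit` (uses trained weights) or an `ei_network`
#'   (initial weights).
#' @param delta_I Added input in Hz (default 10).
#' @param n_perturbed Number of perturbed Pyr neurons, sampled uniformly
#'   without replacement (default 90, capped at NE).
#' @param stimuli Indices into the stimulus grid to probe; defaults to the
#'   full grid.
#' @param seed Seed for the choice of perturbed neurons.
#' @param store_raw Keep the per-stimulus rate differences.
#' @param tol,max_steps Steady-state solver settings.
#' @return An object of class `"ei_influence"`: list with `influence`
#'   (`n_perturbed` by NE matrix of stimulus-averaged influences),
#'   `perturbed` (neuron indices), `delta_I`, `n_stimuli`, optionally
#'   `raw` (array perturbed x NE x stimuli), and `base` (the unperturbed
#'   `ei_responses`).
#' @export
perturb_influence <- function(object, delta_I = 10, n_perturbed = 90,
                              stimuli = NULL, seed = 1L, store_raw = FALSE,
                              tol = 1e-6, max_steps = 1e5) {
  if (inherits(object, "ei_fit")) {
    network <- object$network
    W <- object$W
  } else if (inherits(object, "ei_network")) {
    network <- object
    W <- object$W
  } else {
    stop("'object' must be an 'ei_fit' or an 'ei_network'")
  }
  if (delta_I <= 0) stop("'delta_I' must be positive")
  params <- network$params
  NE <- params$NE
  NS_all <- network$grid$n_stimuli
  if (is.null(stimuli)) stimuli <- seq_len(NS_all)
  n_perturbed <- min(n_perturbed, NE)

  set.seed(as.integer(seed))
  perturbed <- sort(sample.int(NE, n_perturbed))

  M <- .signed_matrix(W)
  base <- response_tensor(network, W = W, tol = tol, max_steps = max_steps)
  base_states <- lapply(stimuli, function(s) {
    ei_state(base$activations[seq_len(NE), s],
             base$activations[NE + seq_len(params$NI), s])
  })

  influence <- matrix(0, n_perturbed, NE)
  raw <- if (store_raw) array(NA_real_, c(n_perturbed, NE, length(stimuli)))
  skipped <- 0L
  for (k in seq_along(perturbed)) {
    i <- perturbed[k]
    acc <- numeric(NE)
    n_ok <- 0L
    for (si in seq_along(stimuli)) {
      s <- stimuli[si]
      inp <- network$inputs[, s]
      inp[i] <- inp[i] + delta_I
      st <- tryCatch(
        steady_state(W, inp, params, state = base_states[[si]], tol = tol,
                     max_steps = max_steps, M = M, on_cycle = "average"),
        error = function(e) NULL)
      if (is.null(st)) {
        skipped <- skipped + 1L
        next
      }
      d <- (st$rE - base$rates[seq_len(NE), s]) / delta_I
      if (store_raw) raw[k, , si] <- d
      acc <- acc + d
      n_ok <- n_ok + 1L
    }
    if (n_ok == 0L) stop("no stimulus converged for perturbed neuron ", i)
    influence[k, ] <- acc / n_ok
  }
  if (skipped > 0L) {
    warning(skipped, " perturbed-neuron/stimulus pairs skipped ",
            "(steady state not reached)")
  }
  structure(list(influence = influence, perturbed = perturbed,
                 delta_I = delta_I, n_stimuli = length(stimuli),
                 raw = raw, base = base),
            class = "ei_influence")
}
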