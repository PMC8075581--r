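#' Cropping threshold matching a target connection density
#'
#' Finds the constant \eqn{C} subtracted from the pairwise input signal
#' correlations before rectification, such that the fraction of strictly
#' positive off-diagonal entries of \eqn{[corr - C]_+} is as close as
#' possible to the target connection probability. Deterministic given the
#' correlation matrix.
#'
#' @param corr Symmetric matrix of signal correlations.
#' @param p_target Target connection probability in (0, 1].
#' @return The threshold `C` (scalar).
#' @export
find_crop_threshold <- function(corr, p_target) {
  if (length(p_target) != 1L || !is.finite(p_target) ||
      p_target <= 0 || p_target > 1) {
    stop("'p_target' must lie in (0, 1]")
  }
  v <- corr[row(corr) != col(corr)]
  if (any(!is.finite(v))) stop("off-diagonal correlations must be finite")
  u <- sort(unique(v))
  # candidate thresholds: below the minimum, and midpoints between
  # consecutive distinct values (fraction above C is piecewise constant)
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2)
  frac <- vapply(cand, function(C) mean(v > C), numeric(1))
  cand[which.min(abs(frac - p_target))]
}

#' Tuned recurrent excitatory connectivity
#'
#' Builds the Pyr-to-Pyr weight matrix: the weight between two neurons grows
#' linearly with the signal correlation of their external inputs,
#' \eqn{W_{ij} = [corr(I_i, I_j) - C]_+}, with `C` chosen by
#' [find_crop_threshold()] so the connection density matches `p`. The
#' diagonal is forced to zero and each row is rescaled to sum to `J_EE`.
#'
#' @param inputs Matrix of external input tuning, neurons by stimuli.
#' @param p Target connection probability.
#' @param J_EE Total incoming excitatory weight per Pyr neuron.
#' @return Nonnegative weight matrix (neurons by neurons).
#' @export
build_pyr_pyr <- function(inputs, p, J_EE) {
  if (nrow(inputs) < 2) stop("need at least 2 Pyr neurons")
  sds <- apply(inputs, 1L, stats::sd)
  if (any(sds == 0)) stop("constant input tuning: correlation undefined")
  cc <- stats::cor(t(inputs))
  C <- find_crop_threshold(cc, p)
  W <- pmax(cc - C, 0)
  diag(W) <- 0
  rs <- rowSums(W)
  if (any(rs == 0)) stop("a Pyr neuron has no incoming tuned connections")
  W * (J_EE / rs)
}

#' Random log-normal weight matrix
#'
#' Draws an independent Bernoulli(`p`) connectivity mask and log-normal
#' weights (log-sd `sigma_log`) on the realised connections, then rescales
#' every row multiplicatively so its sum equals `J`. Rows that come out with
#' no connections are resampled (with a warning). The location parameter of
#' the log-normal is irrelevant because of the row rescaling.
#'
#' @param n_post,n_pre Matrix dimensions (post- by presynaptic).
#' @param p Connection probability in (0, 1].
#' @param J Row total after rescaling.
#' @param sigma_log Standard deviation of the log weights.
#' @param exclude_diag Force a zero diagonal (no self-connections); requires
#'   a square matrix.
#' @return Nonnegative `n_post` by `n_pre` matrix.
#' @export
init_random_weights <- function(n_post, n_pre, p, J, sigma_log,
                                exclude_diag = FALSE) {
  if (n_post < 1 || n_pre < 1) stop("invalid matrix dimensions")
  if (p <= 0 || p > 1) stop("'p' must lie in (0, 1] when J > 0")
  if (sigma_log < 0) stop("'sigma_log' must be >= 0")
  mask <- matrix(stats::runif(n_post * n_pre) < p, n_post, n_pre)
  if (exclude_diag) diag(mask) <- FALSE
  min_row <- if (exclude_diag) 1L else 0L  # a diagonal-only row is still empty
  empty <- which(rowSums(mask) == 0L)
  while (length(empty) > 0L) {
    warning("resampling ", length(empty), " row(s) with no connections")
    for (i in empty) {
      mask[i, ] <- stats::runif(n_pre) < p
      if (exclude_diag) mask[i, i] <- FALSE
    }
    empty <- which(rowSums(mask) == 0L)
  }
  W <- matrix(0, n_post, n_pre)
  n_syn <- sum(mask)
  W[mask] <- exp(stats::rnorm(n_syn, 0, sigma_log))
  W * (J / rowSums(W))
}

#' Construct the recurrent E/I network
#'
#' Builds the stimulus grid, the Pyr tuning, the tuned Pyr-to-Pyr weights and
#' the randomly initialised Pyr-to-PV, PV-to-Pyr and PV-to-PV weights. All
#' weight matrices hold magnitudes (nonnegative); inhibitory signs are
#' applied in the dynamics. Connectivity masks are fixed for the lifetime of
#' the network: plasticity never adds or prunes synapses.
#'
#' @param params A [network_params()].
#' @param seed Integer seed for the random connectivity.
#' @return An object of class `"ei_network"`: list with `params`, `grid`,
#'   `tuning`, `inputs` (NE by NS external input matrix), `W` (list `EE`,
#'   `EI`, `IE`, `II`; `EI` is NE x NI, `IE` is NI x NE), `masks` (logical,
#'   same shapes), and `seed`.
#' @examples
#' net <- ei_network(network_params(NE = 27, NI = 4, n_per_dim = 3), seed = 1)
#' range(rowSums(net$W$IE))  # both 5: row totals are J_IE
#' @export
ei_network <- function(params = network_params(), seed = 1L) {
  stopifnot(inherits(params, "network_params"))
  grid <- stimulus_grid(params$n_per_dim)
  tuning <- pyr_tuning(grid, n_pyr = params$NE, kappa = params$kappa,
                       max_rate = params$max_rate)
  inputs <- input_matrix(tuning, grid)

  set.seed(as.integer(seed))
  W_EE <- build_pyr_pyr(inputs, params$p, params$J_EE)
  W_IE <- init_random_weights(params$NI, params$NE, params$p, params$J_IE,
                              params$sigma_log)
  W_EI <- init_random_weights(params$NE, params$NI, params$p, params$J_EI,
                              params$sigma_log)
  W_II <- init_random_weights(params$NI, params$NI, params$p, params$J_II,
                              params$sigma_log, exclude_diag = TRUE)

  W <- list(EE = W_EE, EI = W_EI, IE = W_IE, II = W_II)
  masks <- lapply(W, function(w) w > 0)
  structure(list(params = params, grid = grid, tuning = tuning,
                 inputs = inputs, W = W, masks = masks,
                 seed = as.integer(seed)),
            class = "ei_network")
}
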