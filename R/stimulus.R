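#' Periodic three-dimensional stimulus grid
#'
#' Builds the discrete stimulus set used throughout the model: an evenly
#' spaced grid on the periodic cube \eqn{[-\pi, \pi)^3}, whose dimensions are
#' interpreted as orientation, temporal frequency and spatial frequency.
#' Grid points sit at \eqn{-\pi + k \cdot 2\pi/n} for \eqn{k = 0, \ldots, n-1}
#' in each dimension, so the grid includes \eqn{-\pi} and excludes \eqn{\pi}.
#'
#' @param n_per_dim Number of grid points per dimension (default 12, giving
#'   1728 stimuli).
#' @return An object of class `"stimulus_grid"`: a list with `points`
#'   (an `n_per_dim^3` by 3 matrix of stimulus coordinates), `n_per_dim`,
#'   and `n_stimuli`.
#' @examples
#' g <- stimulus_grid(4)
#' g$n_stimuli  # 64
#' @export
stimulus_grid <- function(n_per_dim = 12) {
  if (length(n_per_dim) != 1L || !is.finite(n_per_dim) || n_per_dim < 1 ||
      n_per_dim != round(n_per_dim)) {
    stop("'n_per_dim' must be a positive integer")
  }
  n_per_dim <- as.integer(n_per_dim)
  axis <- -pi + (seq_len(n_per_dim) - 1L) * 2 * pi / n_per_dim
  pts <- as.matrix(expand.grid(ori = axis, tf = axis, sf = axis,
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- list(NULL, c("orientation", "temporal_freq", "spatial_freq"))
  structure(list(points = pts, n_per_dim = n_per_dim, n_stimuli = nrow(pts)),
            class = "stimulus_grid")
}

#' Von Mises stimulus tuning of the excitatory population
#'
#' Assigns each pyramidal neuron a preferred stimulus and the parameters of
#' its bell-shaped (von Mises) tuning. Preferred stimuli cover the periodic
#' stimulus space evenly: when the number of neurons equals the number of
#' grid points they coincide with the grid exactly once; otherwise `n_pyr`
#' must be a perfect cube \eqn{m^3} and the preferences tile their own even
#' \eqn{m \times m \times m} grid over the same \eqn{[-\pi,\pi)^3} range
#' (e.g. 512 neurons on an 8x8x8 preference lattice under a 12x12x12
#' stimulus grid).
#'
#' @param grid A [stimulus_grid()].
#' @param n_pyr Number of excitatory neurons (a perfect cube).
#' @param kappa Von Mises concentration (tuning width), default 1.
#' @param max_rate Peak external input in Hz at the preferred stimulus
#'   (default 50).
#' @return An object of class `"pyr_tuning"`: list with `preferred`
#'   (`n_pyr` by 3 matrix), `kappa`, `max_rate`.
#' @export
pyr_tuning <- function(grid, n_pyr = grid$n_stimuli, kappa = 1, max_rate = 50) {
  stopifnot(inherits(grid, "stimulus_grid"))
  if (kappa < 0 || max_rate <= 0) stop("'kappa' must be >= 0, 'max_rate' > 0")
  if (n_pyr == grid$n_stimuli) {
    pref <- grid$points
  } else {
    m <- round(n_pyr^(1 / 3))
    if (m^3 != n_pyr) {
      stop("'n_pyr' must be a perfect cube for even coverage of the stimulus space")
    }
    pref <- stimulus_grid(m)$points
  }
  structure(list(preferred = pref, kappa = kappa, max_rate = max_rate),
            class = "pyr_tuning")
}

#' Tuned external input for a single stimulus
#'
#' Input to Pyr neuron i is the separable product of one-dimensional von
#' Mises factors,
#' \deqn{I_i(s) = I_{max} \prod_d \exp\{\kappa(\cos(s_d - \phi_{i,d}) - 1)\},}
#' which peaks at `max_rate` when the stimulus matches the preference
#' (mod \eqn{2\pi}) and is strictly positive everywhere.
#'
#' @param stimulus Numeric 3-vector of stimulus coordinates.
#' @param tuning A [pyr_tuning()].
#' @return Numeric vector of input rates (Hz), one per Pyr neuron.
#' @export
tuned_input <- function(stimulus, tuning) {
  stopifnot(inherits(tuning, "pyr_tuning"))
  if (length(stimulus) != 3L || any(!is.finite(stimulus))) {
    stop("'stimulus' must be a finite 3-vector")
  }
  d <- sweep(tuning$preferred, 2L, stimulus)  # pref - s, per dim
  tuning$max_rate * exp(tuning$kappa * (rowSums(cos(d)) - 3))
}

#' External input matrix over a stimulus set
#'
#' Evaluates [tuned_input()] for every stimulus of a grid at once.
#'
#' @param tuning A [pyr_tuning()].
#' @param grid A [stimulus_grid()] (or a matrix of stimuli, one per row).
#' @return Matrix of input rates, neurons by stimuli.
#' @export
input_matrix <- function(tuning, grid) {
  pts <- if (inherits(grid, "stimulus_grid")) grid$points else as.matrix(grid)
  acc <- matrix(0, nrow(tuning$preferred), nrow(pts))
  for (d in 1:3) {
    acc <- acc + cos(outer(tuning$preferred[, d], pts[, d], "-"))
  }
  tuning$max_rate * exp(tuning$kappa * (acc - 3))
}
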