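#' Response similarity of two tuning vectors
#'
#' Normalised inner product of two neurons' steady-state responses over the
#' stimulus set,
#' \deqn{RS(r_i, r_j) = \frac{\sum_s r_i(s) r_j(s)}{\|r_i\| \|r_j\|},}
#' which lies in \[0, 1\] for nonnegative rates and equals 1 iff the
#' tunings are proportional.
#'
#' @param r_i,r_j Per-stimulus rate vectors of equal length.
#' @return The RS value (scalar).
#' @export
response_similarity <- function(r_i, r_j) {
  if (length(r_i) != length(r_j)) stop("rate vectors must have equal length")
  ni <- sqrt(sum(r_i^2)); nj <- sqrt(sum(r_j^2))
  if (ni == 0 || nj == 0) stop("response similarity undefined for an all-zero tuning vector")
  sum(r_i * r_j) / (ni * nj)
}

#' Stimulus selectivity (response skewness)
#'
#' Skewness of a neuron's response distribution across stimuli, using
#' population (uncorrected) moments:
#' \deqn{\gamma = \langle (r - \bar r)^3 \rangle / \langle (r - \bar r)^2 \rangle^{3/2}.}
#' A neuron that responds strongly to only a few stimuli has high skewness.
#' A constant response (zero variance) returns 0 with attribute
#' `degenerate = TRUE`: it is maximally unselective.
#'
#' @param r Per-stimulus rate vector (at least 3 stimuli).
#' @return Skewness (scalar), possibly with attribute `degenerate`.
#' @export
stimulus_selectivity <- function(r) {
  if (length(r) < 3L) stop("need at least 3 stimuli")
  m <- mean(r)
  v <- mean((r - m)^2)
  if (v == 0) return(structure(0, degenerate = TRUE))
  mean((r - m)^3) / v^1.5
}

#' Angle between a gradient and its approximation
#'
#' \eqn{\theta = \arccos\left( \langle G, A \rangle_F / (\|G\|_F \|A\|_F) \right)}
#' with the Frobenius inner product; in \[0, pi\]. Used to track how far a
#' local update rule deviates from the gradient-based update it
#' approximates (feedback alignment).
#'
#' @param G,A Matrices of identical shape, both nonzero.
#' @return Angle in radians.
#' @export
update_angle <- function(G, A) {
  if (!all(dim(G) == dim(A))) stop("'G' and 'A' must have the same shape")
  nG <- sqrt(sum(G^2)); nA <- sqrt(sum(A^2))
  if (nG == 0 || nA == 0) stop("angle undefined for a zero matrix")
  acos(max(-1, min(1, sum(G * A) / (nG * nA))))
}

#' Sample reciprocally connected Pyr-PV pairs
#'
#' Draws an experimentally feasible sample of synaptic connections:
#' Pyr-PV pairs connected in both directions whose input (Pyr-to-PV) and
#' output (PV-to-Pyr) weights both exceed the experimental detection
#' threshold. For each sampled pair the response similarity of the two
#' neurons is computed from the response tensor.
#'
#' @param W Weight list (`EI`, `IE` used).
#' @param masks Connectivity mask list.
#' @param responses An `ei_responses` (from [response_tensor()]).
#' @param n Sample size (pairs, without replacement).
#' @param threshold Detection threshold for both weights (default `1e-4`);
#'   with `relative = TRUE` it is interpreted as a fraction of the largest
#'   weight in each matrix.
#' @param relative Use relative thresholds.
#' @return A data.frame with columns `pv`, `pyr`, `w_in` (Pyr-to-PV),
#'   `w_out` (PV-to-Pyr), `rs`.
#' @export
sample_reciprocal_pairs <- function(W, masks, responses, n = 100,
                                    threshold = 1e-4, relative = FALSE) {
  NE <- responses$NE
  th_in <- if (relative) threshold * max(W$IE) else threshold
  th_out <- if (relative) threshold * max(W$EI) else threshold
  # qualifying (pv i, pyr j): both directions present and detectable
  qual <- masks$IE & t(masks$EI) & (W$IE > th_in) & (t(W$EI) > th_out)
  idx <- which(qual, arr.ind = TRUE)
  if (nrow(idx) < n) {
    stop(sprintf("sampling infeasible: only %d qualifying pairs (< %d)",
                 nrow(idx), n))
  }
  take <- idx[sample.int(nrow(idx), n), , drop = FALSE]
  pv <- take[, 1L]; pyr <- take[, 2L]
  rs <- vapply(seq_len(n), function(k) {
    response_similarity(responses$rates[pyr[k], ],
                        responses$rates[NE + pv[k], ])
  }, numeric(1))
  data.frame(pv = pv, pyr = pyr,
             w_in = W$IE[cbind(pv, pyr)],
             w_out = W$EI[cbind(pyr, pv)],
             rs = rs)
}

#' Weight/response-similarity correlations of a synapse sample
#'
#' Pearson correlations (with two-sided p-values) between output weight
#' and RS, input weight and RS, and input and output weight, for one
#' sample of reciprocally connected pairs. A correlation is called highly
#' significant positive when `r > 0` and `p < 0.01`.
#'
#' @param sample Data.frame from [sample_reciprocal_pairs()].
#' @return A data.frame with rows `output_rs`, `input_rs`, `input_output`
#'   and columns `r`, `p`.
#' @export
sample_correlations <- function(sample) {
  if (nrow(sample) < 3L) stop("need at least 3 pairs")
  one <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("correlation undefined: zero-variance column")
    }
    ct <- stats::cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  out <- rbind(output_rs = one(sample$w_out, sample$rs),
               input_rs = one(sample$w_in, sample$rs),
               input_output = one(sample$w_in, sample$w_out))
  as.data.frame(out)
}

#' Fraction of samples with highly significant positive correlations
#'
#' Repeats the pair-sampling analysis `n_resamples` times and reports, for
#' each of the three correlation types, the fraction of samples in which
#' the correlation is positive with two-sided p < 0.01.
#'
#' @inheritParams sample_reciprocal_pairs
#' @param n_resamples Number of independent samples.
#' @param n Pairs per sample.
#' @param seed Integer seed.
#' @return Named numeric vector (`output_rs`, `input_rs`, `input_output`).
#' @export
fraction_significant <- function(W, masks, responses, n_resamples = 10000,
                                 n = 100, threshold = 1e-4, seed = 1L) {
  set.seed(as.integer(seed))
  hits <- c(output_rs = 0, input_rs = 0, input_output = 0)
  for (b in seq_len(n_resamples)) {
    sm <- sample_reciprocal_pairs(W, masks, responses, n = n,
                                  threshold = threshold)
    cc <- sample_correlations(sm)
    hits <- hits + (cc$r > 0 & cc$p < 0.01)
  }
  hits / n_resamples
}

#' Pairwise receptive-field correlation matrix of the Pyr population
#'
#' Pearson correlations between the per-stimulus response vectors of every
#' pair of Pyr neurons. Neurons with constant responses yield undefined
#' correlations; their entries are set to `NA` and flagged.
#'
#' @param responses An `ei_responses`, or a matrix of Pyr rates (neurons
#'   by stimuli).
#' @return Symmetric correlation matrix (attribute `degenerate`: indices
#'   of constant-response neurons, if any).
#' @export
rf_correlation_matrix <- function(responses) {
  r <- if (inherits(responses, "ei_responses")) {
    responses$rates[seq_len(responses$NE), , drop = FALSE]
  } else {
    as.matrix(responses)
  }
  sds <- apply(r, 1L, stats::sd)
  bad <- which(sds == 0)
  cc <- suppressWarnings(stats::cor(t(r)))
  if (length(bad)) {
    cc[bad, ] <- NA_real_
    cc[, bad] <- NA_real_
    diag(cc)[bad] <- 1
    attr(cc, "degenerate") <- bad
  }
  cc
}

#' Mean coefficient of determination over neuron pairs
#'
#' Mean of the squared off-diagonal receptive-field correlations over all
#' unordered distinct pairs: how well, on average, one Pyr neuron's
#' receptive field predicts another's.
#'
#' @param rf_corr Correlation matrix from [rf_correlation_matrix()].
#' @return Scalar in \[0, 1\] (`NA` entries are dropped).
#' @export
mean_r2 <- function(rf_corr) {
  v <- rf_corr[upper.tri(rf_corr)]
  mean(v^2, na.rm = TRUE)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. The reported `U` counts, for
#' the first sample, the number of (x, y) pairs with x > y (ties counted
#' half). The two-sided p-value is computed by exhaustive enumeration of
#' all rank assignments when `max(n, m) <= 8`, and otherwise by the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @return List with `U`, `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  u_stat <- function(rk, n, m) sum(rk[seq_len(n)]) - n * (n + 1) / 2
  rk <- rank(c(x, y))
  U <- u_stat(rk, n, m)
  if (max(n, m) <= 8) {
    sel <- utils::combn(n + m, n)
    us <- apply(sel, 2L, function(ix) sum(rk[ix]) - n * (n + 1) / 2)
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
    method <- "exact enumeration"
  } else {
    N <- n + m
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * (N + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (U - n * m / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, method = method)
}

#' Bin perturbation influence by receptive-field correlation
#'
#' Groups the pairwise influences (perturbed neuron i on measured neuron
#' j, i != j) into bins of the pair's receptive-field correlation and
#' averages within bins.
#'
#' @param influence An `ei_influence`.
#' @param rf_corr Pyr receptive-field correlation matrix (full NE x NE).
#' @param bin_edges Bin boundaries covering \[-1, 1\]; default 10
#'   equal-width bins over the observed correlation range.
#' @param n_bins Number of bins when `bin_edges` is NULL.
#' @return Data.frame with `lo`, `hi`, `mid`, `mean`, `sem`, `n`; empty
#'   bins have `NA` mean and `sem`, single-observation bins `NA` sem.
#' @export
bin_influence <- function(influence, rf_corr, bin_edges = NULL, n_bins = 10) {
  stopifnot(inherits(influence, "ei_influence"))
  NE <- ncol(influence$influence)
  pi_ <- influence$perturbed
  xs <- ys <- numeric(0)
  for (k in seq_along(pi_)) {
    j <- setdiff(seq_len(NE), pi_[k])
    xs <- c(xs, rf_corr[pi_[k], j])
    ys <- c(ys, influence$influence[k, j])
  }
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (is.null(bin_edges)) {
    rng <- range(xs)
    bin_edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  bin <- cut(xs, bin_edges, include.lowest = TRUE)
  agg <- tapply(ys, bin, function(v) {
    c(mean = mean(v),
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v))
  })
  res <- do.call(rbind, lapply(agg, function(a) {
    if (is.null(a)) c(mean = NA_real_, sem = NA_real_, n = 0) else a
  }))
  data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
             mid = (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2,
             mean = res[, "mean"], sem = res[, "sem"], n = res[, "n"],
             row.names = NULL)
}

#' Outgoing Pyr-to-PV weight versus perturbation influence
#'
#' Correlates each perturbed Pyr neuron's total outgoing weight onto the
#' PV population with the mean influence its perturbation has on all
#' other Pyr neurons.
#'
#' @param W Weight list (`IE` used).
#' @param influence An `ei_influence` with at least 3 perturbed neurons.
#' @return List with `r`, `p`, and the underlying data.frame `data`
#'   (columns `neuron`, `w_out_total`, `mean_influence`).
#' @export
outgoing_weight_vs_influence <- function(W, influence) {
  stopifnot(inherits(influence, "ei_influence"))
  pi_ <- influence$perturbed
  if (length(pi_) < 3L) stop("need influence for at least 3 perturbed neurons")
  NE <- ncol(influence$influence)
  w_out <- colSums(W$IE)[pi_]
  mi <- vapply(seq_along(pi_), function(k) {
    mean(influence$influence[k, setdiff(seq_len(NE), pi_[k])])
  }, numeric(1))
  if (stats::sd(w_out) == 0 || stats::sd(mi) == 0) {
    stop("correlation undefined: zero-variance input")
  }
  ct <- stats::cor.test(w_out, mi)
  list(r = unname(ct$estimate), p = ct$p.value,
       data = data.frame(neuron = pi_, w_out_total = w_out,
                         mean_influence = mi))
}
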