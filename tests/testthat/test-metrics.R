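test_that("response similarity is the normalised tuning overlap", {
  r <- c(2, 1, 0.5)
  expect_equal(response_similarity(r, r), 1)
  expect_equal(response_similarity(c(1, 0, 2), c(0, 3, 0)), 0)
  expect_equal(response_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  # scale invariance
  expect_equal(response_similarity(7 * r, r), 1)
  expect_equal(response_similarity(3 * c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(response_similarity(c(0, 0), c(1, 1)), "all-zero")
  expect_error(response_similarity(c(1, 1), c(1, 1, 1)), "equal length")
})

test_that("selectivity is the population skewness of the response distribution", {
  expect_equal(as.numeric(stimulus_selectivity(rep(3, 10))), 0)
  expect_true(attr(stimulus_selectivity(rep(3, 10)), "degenerate"))
  expect_equal(stimulus_selectivity(c(1, 1, 5, 5)), 0)  # symmetric two-level
  expect_equal(stimulus_selectivity(c(0, 0, 0, 1)), 2 / sqrt(3))
  expect_error(stimulus_selectivity(c(1, 2)), "at least 3")
})

test_that("update angle behaves like an angle", {
  G <- matrix(c(1, 2, -1, 0.5), 2, 2)
  expect_equal(update_angle(G, G), 0)
  expect_equal(update_angle(G, -G), pi)
  A <- matrix(c(0, 1, 0, 0), 2, 2)
  B <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(update_angle(A, B), pi / 2)
  # symmetry and scale invariance
  expect_equal(update_angle(G, A), update_angle(A, G))
  expect_equal(update_angle(3 * G, 0.1 * A), update_angle(G, A))
  expect_error(update_angle(G, matrix(0, 2, 2)), "zero matrix")
})

test_that("Mann-Whitney U agrees with exhaustive enumeration and wilcox.test", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U, 4.5)  # n*m/2
  expect_equal(mann_whitney_u(c(1, 3, 5), c(2, 4, 6))$U, 3)

  # exact path vs wilcox.test's exact distribution (no ties)
  set.seed(21)
  for (k in 1:10) {
    x <- sample(100, sample(3:6, 1))
    y <- sample(200:300, sample(3:6, 1))
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }

  # brute-force permutation oracle, including ties
  x <- c(1, 2, 2, 5); y <- c(2, 3, 4)
  got <- mann_whitney_u(x, y)
  rk <- rank(c(x, y))
  sel <- combn(7, 4)
  us <- apply(sel, 2, function(ix) sum(rk[ix]) - 10)
  expect_equal(got$U, sum(rk[1:4]) - 10)
  expect_equal(got$p, min(1, 2 * min(mean(us <= got$U), mean(us >= got$U))))

  # large samples: tie-corrected normal approximation, as wilcox.test with
  # correct = FALSE
  set.seed(22)
  x <- round(rnorm(30, 0, 2)); y <- round(rnorm(25, 1, 2))
  got <- mann_whitney_u(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("receptive-field correlations and mean R^2", {
  r <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  cc <- rf_correlation_matrix(r)
  expect_equal(diag(cc), rep(1, 3))
  expect_equal(cc[1, 2], 1)    # proportional tuning
  expect_equal(cc[1, 3], -1)   # anti-correlated
  expect_equal(cc, t(cc))

  # constant rows are flagged, not silently zeroed
  r2 <- rbind(c(1, 2, 3), c(5, 5, 5))
  cc2 <- rf_correlation_matrix(r2)
  expect_true(is.na(cc2[1, 2]))
  expect_equal(attr(cc2, "degenerate"), 2L)

  # hand-computed mean R^2 and its bounds/permutation invariance
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- 0.5
  M[1, 3] <- M[3, 1] <- 0.1
  M[2, 3] <- M[3, 2] <- -0.3
  expect_equal(mean_r2(M), (0.25 + 0.01 + 0.09) / 3)
  perm <- c(3, 1, 2)
  expect_equal(mean_r2(M[perm, perm]), mean_r2(M))
  expect_equal(mean_r2(diag(2)), 0)
  expect_equal(mean_r2(matrix(1, 4, 4)), 1)
})

test_that("reciprocal pair sampling respects thresholds and reproducibility", {
  set.seed(31)
  NE <- 10; NI <- 3; NS <- 6
  W <- list(EI = matrix(runif(NE * NI, 0.1, 1), NE, NI),
            IE = matrix(runif(NI * NE, 0.1, 1), NI, NE))
  masks <- list(EI = matrix(TRUE, NE, NI), IE = matrix(TRUE, NI, NE))
  resp <- structure(list(rates = matrix(runif((NE + NI) * NS, 0.1, 2),
                                        NE + NI, NS),
                         NE = NE, NI = NI), class = "ei_responses")
  all_pairs <- sample_reciprocal_pairs(W, masks, resp, n = NE * NI)
  expect_equal(nrow(all_pairs), NE * NI)  # n = all qualifying pairs
  expect_true(all(all_pairs$rs >= 0 & all_pairs$rs <= 1))
  # RS column is consistent with direct evaluation
  k <- 7
  expect_equal(all_pairs$rs[k],
               response_similarity(resp$rates[all_pairs$pyr[k], ],
                                   resp$rates[NE + all_pairs$pv[k], ]))

  expect_error(sample_reciprocal_pairs(W, masks, resp, n = 5, threshold = 10),
               "infeasible")

  set.seed(99); s1 <- sample_reciprocal_pairs(W, masks, resp, n = 5)
  set.seed(99); s2 <- sample_reciprocal_pairs(W, masks, resp, n = 5)
  expect_identical(s1, s2)
})

test_that("sample correlations match the textbook Pearson formula", {
  sm <- data.frame(pv = 1:5, pyr = 1:5,
                   w_in = c(0.2, 0.5, 0.3, 0.9, 0.6),
                   w_out = c(0.1, 0.4, 0.35, 0.8, 0.55),
                   rs = c(0.15, 0.5, 0.3, 0.85, 0.6))
  cc <- sample_correlations(sm)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cc["input_rs", "r"], pearson(sm$w_in, sm$rs))
  expect_equal(cc["output_rs", "r"], pearson(sm$w_out, sm$rs))
  expect_equal(cc["input_output", "r"], pearson(sm$w_in, sm$w_out))
  # p-value via the t transform
  r <- pearson(sm$w_in, sm$rs); tt <- r * sqrt(3) / sqrt(1 - r^2)
  expect_equal(cc["input_rs", "p"], 2 * pt(-abs(tt), df = 3))

  sm$w_out <- sm$w_in
  expect_equal(sample_correlations(sm)["input_output", "r"], 1)
  sm$w_in <- 0.5
  expect_error(sample_correlations(sm), "zero-variance")
})

test_that("significance fractions: perfect assembly vs shuffled null", {
  set.seed(41)
  NE <- 30; NI <- 6; NS <- 20
  rates <- matrix(runif((NE + NI) * NS, 0.1, 2), NE + NI, NS)
  resp <- structure(list(rates = rates, NE = NE, NI = NI),
                    class = "ei_responses")
  masks <- list(EI = matrix(TRUE, NE, NI), IE = matrix(TRUE, NI, NE))
  # weights a monotone function of RS: every sample perfectly ordered
  RS <- matrix(0, NI, NE)
  for (i in seq_len(NI)) for (j in seq_len(NE)) {
    RS[i, j] <- response_similarity(rates[j, ], rates[NE + i, ])
  }
  W <- list(EI = t(RS) + 0.01, IE = 2 * RS + 0.01)
  fr <- fraction_significant(W, masks, resp, n_resamples = 50, n = 60,
                             seed = 5)
  expect_equal(unname(fr), c(1, 1, 1))

  # independent weights: positive-significant calls are ~0.5% per tail
  set.seed(42)
  W0 <- list(EI = matrix(runif(NE * NI, 0.1, 1), NE, NI),
             IE = matrix(runif(NI * NE, 0.1, 1), NI, NE))
  fr0 <- fraction_significant(W0, masks, resp, n_resamples = 400, n = 25,
                              seed = 6)
  expect_true(all(fr0 <= 0.03))
})

test_that("influence binning and outgoing-weight correlation", {
  NE <- 12
  perturbed <- c(2, 5, 9)
  rf <- matrix(runif(NE * NE, -1, 1), NE, NE); diag(rf) <- 1
  rf <- (rf + t(rf)) / 2
  inf_const <- structure(list(influence = matrix(0.4, 3, NE),
                              perturbed = perturbed, delta_I = 10,
                              n_stimuli = 8), class = "ei_influence")
  b <- bin_influence(inf_const, rf, n_bins = 5)
  expect_equal(nrow(b), 5)
  expect_true(all(abs(b$mean[b$n > 0] - 0.4) < 1e-12))
  expect_true(all(is.na(b$mean[b$n == 0])))

  # influence equal to minus the rf correlation recovers the identity line
  infm <- matrix(0, 3, NE)
  for (k in 1:3) infm[k, ] <- -rf[perturbed[k], ]
  inf2 <- structure(list(influence = infm, perturbed = perturbed,
                         delta_I = 10, n_stimuli = 8),
                    class = "ei_influence")
  b2 <- bin_influence(inf2, rf, n_bins = 6)
  ok <- b2$n > 0
  expect_true(all(abs(b2$mean[ok] + b2$mid[ok]) <= (b2$hi - b2$lo)[ok] / 2 + 1e-12))

  # single observation: SEM is flagged, not fabricated
  inf1 <- structure(list(influence = matrix(1, 1, 2), perturbed = 1L,
                         delta_I = 10, n_stimuli = 1),
                    class = "ei_influence")
  b1 <- bin_influence(inf1, matrix(c(1, 0.3, 0.3, 1), 2, 2),
                      bin_edges = c(-1, 0, 1))
  expect_true(is.na(b1$sem[b1$n == 1]))

  # noiseless linear relation gives r = -1
  W <- list(IE = matrix(runif(5 * NE, 0.1, 1), 5, NE))
  out_w <- colSums(W$IE)[perturbed]
  infl <- matrix(0, 3, NE)
  for (k in 1:3) infl[k, ] <- -2 * out_w[k]
  inf3 <- structure(list(influence = infl, perturbed = perturbed,
                         delta_I = 10, n_stimuli = 8),
                    class = "ei_influence")
  res <- outgoing_weight_vs_influence(W, inf3)
  expect_equal(res$r, -1)
  # constant outgoing weights: undefined
  W$IE[] <- 0.5
  expect_error(outgoing_weight_vs_influence(W, inf3), "zero-variance")
})
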