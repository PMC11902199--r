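# Dyadic-sum representations: every implied matrix must equal its
# definitional dense oracle, and the structural rank/trace facts must hold.

test_that("window_spec validates and normalises weights", {
  w <- window_spec(21)
  expect_equal(sum(w$weights), 21)
  expect_warning(window_spec(10), "asymmetric")
  wc <- window_spec(21, taper = "cosine")
  expect_equal(sum(wc$weights), 21)
  expect_true(all(wc$weights >= 0))
  expect_lt(wc$weights[1], wc$weights[11])  # smooth edges
  expect_error(window_spec(5, weights = c(1, 1)), "length T")
  expect_error(window_spec(3, weights = c(-1, 1, 1)), "nonnegative")
})

test_that("windowed correlation factors imply the Pearson matrix", {
  set.seed(10)
  x <- signal_set(matrix(rnorm(6 * 120), 6, 120))
  f <- dfc_factors(x, "correlation", window = 21)
  for (t in c(11, 60, 110)) {
    expect_equal(reconstruct_dense(f, t),
                 oracle_dense("correlation", x$data, t, 21),
                 tolerance = 1e-10)
  }
  ## proportional rows correlate perfectly
  y <- signal_set(rbind(1:30, 3 * (1:30) + 2, rnorm(30)))
  fy <- dfc_factors(y, "correlation", window = 11)
  expect_equal(reconstruct_dense(fy, 10)[1, 2], 1, tolerance = 1e-12)
  expect_error(factor_matrix(f, 5), "outside valid range")
})

test_that("tapered correlation windows keep unit diagonal and match the
           weighted formula", {
  set.seed(11)
  x <- signal_set(matrix(rnorm(5 * 80), 5, 80))
  w <- window_spec(21, taper = "cosine")
  f <- dfc_factors(x, "correlation", window = w)
  C <- reconstruct_dense(f, 40)
  expect_equal(diag(C), rep(1, 5), tolerance = 1e-10)
  expect_equal(C, oracle_dense("correlation", x$data, 40, 21,
                               weights = w$weights),
               tolerance = 1e-10)
})

test_that("spearman factors imply the rank-correlation matrix", {
  set.seed(12)
  x <- signal_set(matrix(rnorm(4 * 80), 4, 80))
  f <- dfc_factors(x, "correlation", window = 21, variant = "spearman")
  t <- 40
  W <- x$data[, 30:50]
  expect_equal(reconstruct_dense(f, t), cor(t(W), method = "spearman"),
               tolerance = 1e-10)
})

test_that("partial factors imply the sign-normalised precision matrix", {
  set.seed(13)
  x <- signal_set(matrix(rnorm(5 * 100), 5, 100))
  f <- dfc_factors(x, "correlation", window = 21, variant = "partial")
  t <- 50
  R <- cor(t(x$data[, 40:60]))
  Ri <- solve(R)
  d <- sqrt(diag(Ri))
  expect_equal(reconstruct_dense(f, t), Ri / outer(d, d), tolerance = 1e-8)
  expect_error(dfc_factors(x, "correlation", window = 5,
                           variant = "partial"), "T - 1 >= N")
})

test_that("covariance factors imply the windowed sample covariance", {
  set.seed(14)
  x <- signal_set(matrix(rnorm(6 * 150), 6, 150))
  f <- dfc_factors(x, "covariance", window = 21)
  for (t in c(11, 75, 140)) {
    expect_equal(reconstruct_dense(f, t),
                 oracle_dense("covariance", x$data, t, 21),
                 tolerance = 1e-10)
  }
  ## independent unit-variance rows: long window approaches the diagonal
  set.seed(15)
  z <- signal_set(matrix(rnorm(4 * 1001), 4, 1001))
  fz <- dfc_factors(z, "covariance", window = 1001)
  C <- reconstruct_dense(fz, 501)
  expect_lt(max(abs(C - diag(diag(C)))), 3 / sqrt(1001))
})

test_that("cofluctuation factors are rank one and average to the static
           correlation", {
  set.seed(16)
  x <- signal_set(matrix(rnorm(5 * 300), 5, 300))
  f <- dfc_factors(x, "cofluctuation")
  z <- zscore_signals(x)$data
  expect_equal(reconstruct_dense(f, 17), tcrossprod(z[, 17]),
               tolerance = 1e-12)
  acc <- 0
  for (t in valid_frames(f)) acc <- acc + reconstruct_dense(f, t)
  expect_equal(acc / (ncol(z) - 1), cor(t(x$data)), tolerance = 1e-10)
})

test_that("phase alignment factors imply cosines of phase differences", {
  th <- random_phases(5, 20, seed = 17)
  ph <- phase_set(th)
  f <- dfc_factors(ph, "ipa")
  expect_equal(reconstruct_dense(f, 7), oracle_dense("ipa", th, 7),
               tolerance = 1e-12)
  ## equal phases: all-ones matrix; antiphase pair: -1 entry
  th2 <- matrix(0.3, 4, 3)
  th2[2, ] <- 0.3 + pi
  f2 <- dfc_factors(phase_set(th2), "ipa")
  C <- reconstruct_dense(f2, 2)
  expect_equal(C[1, 3], 1, tolerance = 1e-12)
  expect_equal(C[1, 2], -1, tolerance = 1e-12)
})

test_that("phase locking factors match the dense Hermitian average", {
  th <- random_phases(5, 40, seed = 18)
  ph <- phase_set(th)
  f <- dfc_factors(ph, "phase_locking", window = 9)
  C <- reconstruct_dense(f, 20)
  expect_equal(C, oracle_dense("phase_locking", th, 20, 9),
               tolerance = 1e-12)
  expect_equal(diag(Re(C)), rep(1, 5), tolerance = 1e-12)
  ## window 1: real part equals the phase-alignment matrix
  f1 <- suppressWarnings(dfc_factors(ph, "phase_locking", window = 1))
  fi <- dfc_factors(ph, "ipa")
  expect_equal(Re(reconstruct_dense(f1, 20)), reconstruct_dense(fi, 20),
               tolerance = 1e-12)
  ## constant phase offsets across the window: perfect locking
  tho <- matrix(rep(c(0, 1, 2), 10), 3, 10)
  fo <- dfc_factors(phase_set(tho), "phase_locking", window = 5)
  expect_equal(Mod(reconstruct_dense(fo, 5)), matrix(1, 3, 3),
               tolerance = 1e-12)
})

test_that("wavelet coherence factors match the dense Hermitian average", {
  cf <- random_coeffs(4, 30, seed = 19)
  wf <- wavelet_frame(cf, f = 0.1)
  f <- dfc_factors(wf, "wavelet_coherence", window = 7)
  expect_equal(reconstruct_dense(f, 15),
               oracle_dense("wavelet_coherence", cf, 15, 7),
               tolerance = 1e-12)
  ## identical signals: all entries have modulus 1
  cf2 <- rbind(cf[1, ], cf[1, ], cf[1, ])
  f2 <- dfc_factors(wavelet_frame(cf2, f = 0.1), "wavelet_coherence",
                    window = 7)
  expect_equal(Mod(reconstruct_dense(f2, 15)), matrix(1, 3, 3),
               tolerance = 1e-12)
  ## window 1 is a single dyad: rank 1
  f3 <- suppressWarnings(dfc_factors(wf, "wavelet_coherence", window = 1))
  fr <- tcevd_frame(f3, 15)
  expect_equal(fr$rank_estimate, 1L)
  cf0 <- cf; cf0[2, 5] <- 0
  expect_error(dfc_factors(wavelet_frame(cf0, f = 0.1),
                           "wavelet_coherence", window = 7),
               "row 2, frame 5")
})

test_that("implied matrices are PSD with the structural ranks and traces", {
  set.seed(20)
  x <- signal_set(matrix(rnorm(12 * 80), 12, 80))
  th <- random_phases(12, 80, seed = 21)
  wf <- random_coeffs(12, 80, seed = 22)
  cases <- list(
    list(f = dfc_factors(x, "correlation", window = 9), rank_max = 8,
         trace = 12),
    list(f = dfc_factors(x, "covariance", window = 9), rank_max = 8,
         trace = NA),
    list(f = dfc_factors(x, "cofluctuation"), rank_max = 1, trace = NA),
    list(f = dfc_factors(phase_set(th), "ipa"), rank_max = 2, trace = 12),
    list(f = dfc_factors(phase_set(th), "phase_locking", window = 9),
         rank_max = 9, trace = 12),
    list(f = dfc_factors(wavelet_frame(wf, f = 0.1), "wavelet_coherence",
                         window = 9), rank_max = 9, trace = 12))
  for (cs in cases) {
    for (t in c(40, 41)) {
      C <- reconstruct_dense(cs$f, t)
      ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8 * max(ev))
      expect_lte(sum(ev > 1e-10 * max(ev)), cs$rank_max)
      if (!is.na(cs$trace)) expect_equal(sum(ev), cs$trace,
                                         tolerance = 1e-8)
    }
  }
  ## phase alignment rank is exactly 2 for generic phases, N >= 3
  ev <- eigen(reconstruct_dense(dfc_factors(phase_set(th), "ipa"), 40),
              symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-10 * max(ev)), 2L)
})
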