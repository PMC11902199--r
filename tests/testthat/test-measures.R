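# Eigenspace measures against their dense definitional oracles, plus the
# metric, ordering and invariance properties they must satisfy.

make_cov_frames <- function(N, T_w, n, seed) {
  set.seed(seed)
  x <- signal_set(matrix(rnorm(N * (n * T_w + 40)), N, n * T_w + 40))
  f <- dfc_factors(x, "covariance", window = T_w)
  ts <- round(seq(T_w, n * T_w + 30, length.out = n))
  list(frames = lapply(ts, function(t) tcevd_frame(f, t)),
       dense = lapply(ts, function(t) reconstruct_dense(f, t)))
}

test_that("schatten norms follow their spectral definitions", {
  fr <- evd_frame(c(3, 1), diag(2))
  expect_equal(schatten_norm(fr, 1), 4)
  expect_equal(schatten_norm(fr, 2), sqrt(10))
  expect_equal(schatten_norm(fr, Inf), 3)
  expect_error(schatten_norm(evd_frame(numeric(0), matrix(0, 2, 0)), 1),
               "empty")
  ## correlation frames have trace norm N; cofluctuation norms all coincide
  set.seed(40)
  x <- signal_set(matrix(rnorm(8 * 60), 8, 60))
  fit <- dfc(x, "correlation", window = 11)
  expect_equal(unname(schatten_norm(fit, 1)),
               rep(8, length(fit$frames)), tolerance = 1e-8)
  fitc <- dfc(x, "cofluctuation")
  z2 <- colSums(zscore_signals(x)$data^2)
  for (p in c(1, 2, Inf)) {
    expect_equal(unname(schatten_norm(fitc, p)), z2, tolerance = 1e-10)
  }
  ## ordering: inf <= 2 <= 1 on every frame
  fcv <- dfc(x, "covariance", window = 11)
  expect_true(all(schatten_norm(fcv, Inf) <= schatten_norm(fcv, 2) + 1e-12))
  expect_true(all(schatten_norm(fcv, 2) <= schatten_norm(fcv, 1) + 1e-12))
})

test_that("metastability is the sample sd of the norm series", {
  expect_equal(metastability(c(1, 3)), sqrt(2))
  expect_equal(metastability(rep(2, 10)), 0)
  expect_error(metastability(3), ">= 2 frames")
})

test_that("regime switching raises norm metastability over stationarity", {
  wins <- 0L
  for (s in 1:20) {
    covs <- lapply(1:5, function(i) random_spd(10, seed = 1000 + s * 10 + i))
    switching <- planted_covariance_signals(10, 5, 200, seed = s,
                                            covariances = covs)
    stationary <- planted_covariance_signals(10, 5, 200, seed = s,
                                             covariances = covs[rep(1, 5)])
    m_sw <- metastability(dfc(switching$signals, "covariance", window = 61))
    m_st <- metastability(dfc(stationary$signals, "covariance", window = 61))
    wins <- wins + (m_sw > m_st)
  }
  ## sign test at 20 paired seeds: 15+ wins is p < 0.05 one-sided
  expect_gte(wins, 15L)
})

test_that("distances match dense vectorised oracles and are metrics", {
  A <- evd_frame(1, matrix(c(1, 0), 2, 1))
  B <- evd_frame(1, matrix(c(0, 1), 2, 1))
  expect_equal(dfc_distance(A, B, 1), 2)
  expect_equal(dfc_distance(A, B, 2), sqrt(2))
  expect_equal(dfc_distance(A, B, Inf), 1)
  expect_equal(dfc_distance(A, A, 2), 0)
  mk <- make_cov_frames(10, 11, 4, seed = 41)
  for (i in 1:3) {
    d2 <- dfc_distance(mk$frames[[i]], mk$frames[[i + 1]], 2)
    expect_equal(d2, sqrt(sum((mk$dense[[i]] - mk$dense[[i + 1]])^2)),
                 tolerance = 1e-8)
    expect_equal(d2, dfc_distance(mk$frames[[i]], mk$frames[[i + 1]], 2,
                                  method = "inner"), tolerance = 1e-8)
  }
  ## symmetry and triangle inequality on sampled triples
  for (p in c(1, 2, Inf)) {
    d12 <- dfc_distance(mk$frames[[1]], mk$frames[[2]], p)
    d21 <- dfc_distance(mk$frames[[2]], mk$frames[[1]], p)
    d13 <- dfc_distance(mk$frames[[1]], mk$frames[[3]], p)
    d23 <- dfc_distance(mk$frames[[2]], mk$frames[[3]], p)
    expect_equal(d12, d21, tolerance = 1e-10)
    expect_lte(d13, d12 + d23 + 1e-8)
  }
  ## normalised distances rescale both frames to unit p-norm
  dn <- dfc_distance(mk$frames[[1]], mk$frames[[2]], 2, normalise = TRUE)
  n1 <- schatten_norm(mk$frames[[1]], 2); n2 <- schatten_norm(mk$frames[[2]], 2)
  expect_equal(dn, sqrt(sum((mk$dense[[1]] / n1 - mk$dense[[2]] / n2)^2)),
               tolerance = 1e-8)
  ## trace-norm distance between unit-diagonal matrices warns
  ua <- evd_frame(1, matrix(c(1, 0), 2, 1), unit_diagonal = TRUE)
  ub <- evd_frame(1, matrix(c(0, 1), 2, 1), unit_diagonal = TRUE)
  expect_warning(dfc_distance(ua, ub, 1), "degenerate")
})

test_that("frobenius product, alignment and projector distance match dense
           constructions", {
  mk <- make_cov_frames(50, 9, 2, seed = 42)
  A <- mk$frames[[1]]; B <- mk$frames[[2]]
  CA <- mk$dense[[1]]; CB <- mk$dense[[2]]
  expect_equal(frobenius_inner(A, B), sum(CA * CB), tolerance = 1e-8)
  expect_equal(frobenius_inner(A, A), schatten_norm(A, 2)^2,
               tolerance = 1e-8)
  expect_equal(cosine_alignment(A, B),
               sum(CA * CB) / sqrt(sum(CA^2) * sum(CB^2)), tolerance = 1e-8)
  expect_equal(cosine_alignment(A, A), 1, tolerance = 1e-12)
  ## invariance under positive rescaling
  A2 <- A; A2$values <- 3.7 * A2$values
  expect_equal(cosine_alignment(A2, B), cosine_alignment(A, B),
               tolerance = 1e-12)
  ## orthogonal dyads: zero product, zero alignment, sqrt(2) projector gap
  e1 <- evd_frame(2, matrix(c(1, 0), 2, 1))
  e2 <- evd_frame(5, matrix(c(0, 1), 2, 1))
  expect_equal(frobenius_inner(e1, e2), 0)
  expect_equal(cosine_alignment(e1, e2), 0)
  expect_equal(projector_distance(e1, e2, 1), sqrt(2))
  expect_equal(projector_distance(A, A, 3), 0, tolerance = 1e-10)
  ## dense projector oracle
  r <- 3
  PA <- tcrossprod(A$vectors[, 1:r]); PB <- tcrossprod(B$vectors[, 1:r])
  expect_equal(projector_distance(A, B, r), norm(PA - PB, "F"),
               tolerance = 1e-8)
  expect_error(projector_distance(A, B, 100), "exceeds")
})

test_that("von Neumann entropy behaves like a spectral Shannon entropy", {
  expect_equal(von_neumann_entropy(evd_frame(7, matrix(1, 1, 1))), 0)
  expect_equal(von_neumann_entropy(evd_frame(c(0.5, 0.5), diag(2))), log(2))
  expect_equal(von_neumann_entropy(evd_frame(rep(2, 6), diag(6))), log(6))
  expect_equal(von_neumann_entropy(evd_frame(c(0.5, 0.5), diag(2)),
                                   base = 2), 1)
  expect_error(von_neumann_entropy(evd_frame(c(1, -0.5), diag(2))), "PSD")
  ## entropy is bounded by log rank and truncation drives it to zero
  set.seed(43)
  x <- signal_set(matrix(rnorm(8 * 80), 8, 80))
  fit <- dfc(x, "covariance", window = 9)
  ent <- von_neumann_entropy(fit)
  expect_true(all(ent >= 0 & ent <= log(fit$rank) + 1e-12))
  fit1 <- dfc(x, "covariance", window = 9, n_eigs = 1)
  expect_true(all(von_neumann_entropy(fit1) == 0))
  ## tapered windows shape the spectrum: flagged to the user
  fit_t <- dfc(x, "covariance", window = window_spec(9, taper = "cosine"))
  expect_warning(von_neumann_entropy(fit_t), "taper")
})

test_that("measures are invariant to eigenvector sign flips", {
  mk <- make_cov_frames(10, 9, 2, seed = 44)
  A <- mk$frames[[1]]; B <- mk$frames[[2]]
  Bf <- B
  Bf$vectors <- Bf$vectors %*% diag((-1)^seq_along(Bf$values))
  expect_equal(frobenius_inner(A, Bf), frobenius_inner(A, B),
               tolerance = 1e-10)
  expect_equal(dfc_distance(A, Bf, Inf), dfc_distance(A, B, Inf),
               tolerance = 1e-10)
  expect_equal(projector_distance(A, Bf, 2), projector_distance(A, B, 2),
               tolerance = 1e-10)
})

test_that("reconfiguration speed is zero for static series and peaks at
           regime boundaries", {
  ## time-constant phases: identical frames, zero speed
  th <- matrix(rep(runif(6, -pi, pi), 30), 6, 30)
  fit <- dfc(phase_set(th), "ipa")
  s <- reconfiguration_speed(fit, tau = 3, p = 2)
  expect_lt(max(s), 1e-10)
  expect_equal(length(s), 27L)
  expect_error(reconfiguration_speed(fit, tau = 30), "tau")
  ## two-regime benchmark: the largest peak sits at the boundary
  bench <- planted_covariance_signals(8, 2, 300, seed = 45)
  fitb <- dfc(bench$signals, "covariance", window = 61)
  sp <- reconfiguration_speed(fitb, tau = 50, p = 2, normalise = TRUE)
  pk <- find_peaks(sp, min_sep = 61)
  expect_lt(abs(as.integer(names(sp)[pk[1]]) - bench$boundaries[1]), 61)
  ## normalisation only rescales per-frame
  s_raw <- reconfiguration_speed(fitb, tau = 50, p = 2)
  expect_false(isTRUE(all.equal(s_raw, sp)))
  expect_equal(length(s_raw), length(sp))
})

test_that("the FCD matrix is a valid strided distance matrix", {
  th <- matrix(rep(runif(5, -pi, pi), 20), 5, 20)
  fit0 <- dfc(phase_set(th), "ipa")
  D0 <- fcd_matrix(fit0, p = 2)
  ## identical frames cancel to rounding error (sqrt of an eps-level
  ## difference of squared norms)
  expect_lt(max(D0), 1e-6)
  set.seed(46)
  x <- signal_set(matrix(rnorm(10 * 120), 10, 120))
  fit <- dfc(x, "covariance", window = 11)
  D <- fcd_matrix(fit, p = 2, stride = 5)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  ## p = 2 equals dense vectorised pairwise Euclidean distances
  f <- dfc_factors(x, "covariance", window = 11)
  ts <- as.integer(rownames(D))
  for (i in c(1, 4)) {
    for (j in c(2, 8)) {
      expect_equal(D[i, j],
                   sqrt(sum((reconstruct_dense(f, ts[i]) -
                             reconstruct_dense(f, ts[j]))^2)),
                   tolerance = 1e-8)
    }
  }
  ## triangle inequality on sampled triples, p = Inf route included
  Di <- fcd_matrix(fit, p = Inf, stride = 10)
  for (tri in list(c(1, 2, 3), c(2, 5, 9))) {
    expect_lte(Di[tri[1], tri[3]],
               Di[tri[1], tri[2]] + Di[tri[2], tri[3]] + 1e-8)
  }
  expect_error(fcd_matrix(fit, stride = 1, max_entries = 100), "stride")
})

test_that("FCD separates planted regimes", {
  bench <- planted_covariance_signals(8, 3, 250, seed = 47)
  fit <- dfc(bench$signals, "covariance", window = 61)
  for (p in c(2, Inf)) {
    D <- fcd_matrix(fit, p = p, normalise = TRUE, stride = 10)
    lab <- bench$labels[as.integer(rownames(D))]
    same <- outer(lab, lab, "==") & upper.tri(D)
    diffm <- (!outer(lab, lab, "==")) & upper.tri(D)
    expect_lt(mean(D[same]), mean(D[diffm]))
  }
})

test_that("entry time-course similarity finds the expected structure", {
  set.seed(48)
  x <- signal_set(matrix(rnorm(6 * 800), 6, 800), dt = 1)
  ## identical types agree perfectly at every window
  s0 <- matrix_timecourse_similarity(x, "correlation", "correlation",
                                     windows = c(11, 21), n_pairs = 4,
                                     seed = 1)
  expect_equal(s0$similarity, c(1, 1), tolerance = 1e-12)
  ## co-fluctuation looks like a covariance with the window shrinking to 1
  s1 <- matrix_timecourse_similarity(x, "cofluctuation", "covariance",
                                     windows = c(3, 11, 31, 61),
                                     n_pairs = 6, seed = 2)
  expect_equal(which.max(s1$similarity), 1L)
  expect_true(all(diff(s1$similarity) < 0))
  expect_error(matrix_timecourse_similarity(x, "ipa", "correlation",
                                            windows = 11), "band")
})

test_that("lowering the band moves the phase/correlation match to larger
           windows", {
  x <- iid_gaussian_signals(8, 3000, seed = 7, dt = 1)
  wins <- seq(5, 101, by = 8)
  lo <- matrix_timecourse_similarity(x, "ipa", "correlation", wins,
                                     band = c(0.02, 0.05), n_pairs = 8,
                                     seed = 1)
  hi <- matrix_timecourse_similarity(x, "ipa", "correlation", wins,
                                     band = c(0.08, 0.15), n_pairs = 8,
                                     seed = 1)
  w_lo <- lo$window[which.max(lo$similarity)]
  w_hi <- hi$window[which.max(hi$similarity)]
  expect_gt(w_lo, w_hi)
  expect_gt(max(lo$similarity), 0.7)
  expect_gt(max(hi$similarity), 0.7)
})
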