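# Independent dense oracles: every matrix type evaluated entry by entry from
# its defining formula, without touching the factor/Gram machinery.

## centred window indices around frame t
oracle_window <- function(t, T_w) {
  h_l <- (T_w - 1L) %/% 2L
  seq.int(t - h_l, t + (T_w - 1L - h_l))
}

## dense matrix of a given type at frame t, straight from the definitions
oracle_dense <- function(type, dat, t, T_w = NULL, weights = NULL) {
  switch(type,
    correlation = {
      W <- dat[, oracle_window(t, T_w), drop = FALSE]
      if (is.null(weights)) {
        stats::cor(t(W))
      } else {
        w <- weights * T_w / sum(weights)
        mu <- as.vector(W %*% w) / T_w
        Y <- W - mu
        S <- (Y %*% (w * t(Y))) / (T_w - 1)
        d <- sqrt(diag(S))
        S / outer(d, d)
      }
    },
    covariance = {
      W <- dat[, oracle_window(t, T_w), drop = FALSE]
      if (is.null(weights)) {
        stats::cov(t(W))
      } else {
        w <- weights * T_w / sum(weights)
        mu <- as.vector(W %*% w) / T_w
        Y <- W - mu
        (Y %*% (w * t(Y))) / (T_w - 1)
      }
    },
    cofluctuation = {
      z <- (dat - rowMeans(dat)) / apply(dat, 1L, sd)
      tcrossprod(z[, t])
    },
    ipa = {
      th <- dat[, t]
      cos(outer(th, th, "-"))
    },
    phase_locking = {
      cols <- oracle_window(t, T_w)
      out <- 0
      for (tau in cols) {
        e <- exp(1i * dat[, tau])
        out <- out + e %*% Conj(t(e))
      }
      out / T_w
    },
    wavelet_coherence = {
      cols <- oracle_window(t, T_w)
      out <- 0
      for (tau in cols) {
        v <- dat[, tau] / Mod(dat[, tau])
        out <- out + v %*% Conj(t(v))
      }
      out / T_w
    },
    stop("unknown type"))
}

## circular concentration of the pairwise phase difference (phase-locking
## value): 1 when two phase series agree up to a constant offset
plv <- function(a, b) Mod(mean(exp(1i * (a - b))))

wrap_to_pi <- function(x) (x + pi) %% (2 * pi) - pi

## Frobenius norm valid for complex matrices too
fnorm <- function(M) sqrt(sum(Mod(M)^2))

## signed spectrum entries above a relative tolerance
nonnull_spectrum <- function(ev, tol = 1e-8) {
  ev[abs(ev) > tol * max(abs(ev))]
}

## dense eigendecomposition of a reconstructed frame, descending, nulls kept
oracle_evd <- function(C, tol = 1e-10) {
  e <- eigen((C + Conj(t(C))) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  list(values = e$values[keep], vectors = e$vectors[, keep, drop = FALSE])
}

## random phase matrix
random_phases <- function(N, T_rec, seed) {
  set.seed(seed)
  matrix(runif(N * T_rec, -pi, pi), N, T_rec)
}

## random complex coefficient matrix with safely nonzero modulus
random_coeffs <- function(N, T_rec, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(N * T_rec), imaginary = rnorm(N * T_rec)),
         N, T_rec) + 2 + 2i
}

## evd_frame straight from a dense symmetric matrix (for measure oracles)
frame_from_dense <- function(C, frame = 1L, unit_diagonal = FALSE) {
  e <- oracle_evd(C)
  evd_frame(e$values, e$vectors, frame = frame,
            unit_diagonal = unit_diagonal)
}

## mean silhouette width of labelled points given a distance matrix
silhouette_mean <- function(D, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
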