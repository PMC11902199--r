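# Ground-truth-bearing synthetic inputs: the planted-covariance benchmark
# and i.i.d. Gaussian signals for oracle and scaling tests.

#' Random symmetric positive-definite matrix
#'
#' A well-conditioned Wishart-type draw: `S = A A^T / N + 0.1 I` with `A`
#' an `N x N` matrix of i.i.d. standard normals. The ridge keeps the
#' smallest eigenvalue bounded away from zero so Cholesky factors always
#' exist.
#'
#' @param N dimension.
#' @param seed optional integer seed.
#' @return an `N x N` SPD matrix.
#' @export
random_spd <- function(N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(N * N), N, N)
  S <- tcrossprod(A) / N + 0.1 * diag(N)
  (S + t(S)) / 2
}

#' Structured SPD matrices for entropy contrasts
#'
#' `"isotropic"`: near-identity covariance (all axes of variation equally
#' important, high spectral entropy). `"dominant"`: one large eigenvalue on
#' a random axis over a small isotropic floor (low spectral entropy).
#'
#' @param N dimension.
#' @param kind `"isotropic"` or `"dominant"`.
#' @param seed optional integer seed.
#' @return an `N x N` SPD matrix.
#' @export
structured_spd <- function(N, kind = c("isotropic", "dominant"),
                           seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "isotropic") {
    A <- matrix(rnorm(N * N), N, N)
    S <- diag(N) + 0.02 * tcrossprod(A) / N
  } else {
    v <- rnorm(N)
    v <- v / sqrt(sum(v^2))
    S <- 0.1 * diag(N) + N * tcrossprod(v)
  }
  (S + t(S)) / 2
}

#' Planted-covariance benchmark signals
#'
#' Generates zero-mean unit-variance Gaussian signals split into `n_states`
#' contiguous chunks of `chunk_len` frames; each chunk is multiplied by the
#' Cholesky factor of a distinct random SPD matrix, planting a known
#' covariance on each regime. The defaults (10 signals, 5 chunks of 1000
#' frames) give a 10 x 5000 recording with regime switches after frames
#' 1000, 2000, 3000 and 4000.
#'
#' @param N number of signals (default 10).
#' @param n_states number of regimes (default 5).
#' @param chunk_len frames per regime (default 1000, must exceed `N`).
#' @param seed optional integer seed; fixed seeds give bit-identical output.
#' @param covariances optional list of `n_states` SPD matrices to plant
#'   (default: independent [random_spd()] draws).
#' @return an object of class `planted_benchmark`: a list with `signals`
#'   (a [signal_set()]), `covariances`, `boundaries` (last frame of each
#'   regime but the final one), `labels` (regime id per frame) and `seed`.
#' @export
planted_covariance_signals <- function(N = 10L, n_states = 5L,
                                       chunk_len = 1000L, seed = NULL,
                                       covariances = NULL) {
  if (N < 2L || n_states < 2L) stop_value("need N >= 2 and n_states >= 2")
  if (chunk_len <= N) stop_value("chunk_len must exceed N")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariances)) {
    covariances <- lapply(seq_len(n_states), function(i) random_spd(N))
  }
  if (length(covariances) != n_states) {
    stop_value("need one covariance per state")
  }
  chunks <- lapply(seq_len(n_states), function(c) {
    S <- covariances[[c]]
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    stopifnot("planted covariance must be SPD" = ev_min > 0)
    L <- t(chol(S))
    L %*% matrix(rnorm(N * chunk_len), N, chunk_len)
  })
  sig <- signal_set(do.call(cbind, chunks))
  structure(list(signals = sig, covariances = covariances,
                 boundaries = chunk_len * seq_len(n_states - 1L),
                 labels = rep(seq_len(n_states), each = chunk_len),
                 N = N, n_states = n_states, chunk_len = chunk_len,
                 seed = seed),
            class = "planted_benchmark")
}

#' @export
print.planted_benchmark <- function(x, ...) {
  cat("<planted_benchmark> ", x$N, " signals x ",
      x$n_states * x$chunk_len, " frames, ", x$n_states,
      " regimes, switches after frames ",
      paste(x$boundaries, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Independent standard-Gaussian signals
#'
#' @param N number of signals.
#' @param T_rec number of frames.
#' @param seed optional integer seed.
#' @param dt optional sampling interval.
#' @return a [signal_set()] of i.i.d. `N(0, 1)` entries.
#' @export
iid_gaussian_signals <- function(N, T_rec, seed = NULL, dt = NULL) {
  if (!is.null(seed)) set.seed(seed)
  signal_set(matrix(rnorm(N * T_rec), N, T_rec), dt = dt)
}

#' Export a benchmark as plain-text fixture files
#'
#' Writes the signals as CSV and the planted covariances, boundaries and
#' seed as a JSON sidecar, so a run can be replayed as a fixture.
#'
#' @param bench a [planted_covariance_signals()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, "signals.csv")
  meta_path <- file.path(dir, "benchmark.json")
  write_atomic(sig_path, function(p)
    write.csv(as.matrix(bench$signals), p, row.names = FALSE))
  write_atomic(meta_path, function(p)
    jsonlite::write_json(list(covariances = bench$covariances,
                              boundaries = bench$boundaries,
                              N = bench$N, n_states = bench$n_states,
                              chunk_len = bench$chunk_len,
                              seed = bench$seed),
                         p, digits = NA, auto_unbox = TRUE))
  invisible(c(signals = sig_path, meta = meta_path))
}
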