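# Signal containers and preprocessing: z-scoring, rank transform, band-pass
# filtering, analytic-signal phases and Morlet wavelet coefficients.

#' Multivariate signal container
#'
#' Holds an `N x T_rec` matrix of real-valued signals, one row per spatial
#' location (region, voxel, electrode), one column per time frame. Rows
#' containing non-finite values, or rows that are identically zero, are
#' dropped at construction with a message reporting the count; such rows
#' typically correspond to tissue boundaries or dead channels.
#'
#' @param data numeric matrix (N signals x T_rec frames) or an object
#'   coercible to one.
#' @param dt sampling interval in seconds. Optional; required only by
#'   frequency-domain operations ([bandpass()], [instantaneous_phase()],
#'   [wavelet_coefficients()]).
#' @param labels optional character vector of per-signal identifiers.
#' @return an object of class `signal_set`.
#' @examples
#' x <- signal_set(matrix(rnorm(40), 4, 10), dt = 1)
#' dim(x)
#' @export
signal_set <- function(data, dt = NULL, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stop_value("signal_set needs at least 2 signals and 2 frames, got ",
               nrow(data), " x ", ncol(data))
  }
  bad <- apply(data, 1L, function(r) any(!is.finite(r)) || all(r == 0))
  if (any(bad)) {
    message(sum(bad), " row(s) with missing or all-zero values dropped")
    data <- data[!bad, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[!bad]
    if (nrow(data) < 2L) stop_value("fewer than 2 usable signals remain")
  }
  if (!is.null(dt)) {
    if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
      stop_value("dt must be a single positive number (seconds)")
    }
  }
  if (!is.null(labels) && length(labels) != nrow(data)) {
    stop_value("labels length does not match number of retained signals")
  }
  structure(list(data = data, dt = dt, labels = labels,
                 provenance = list()),
            class = "signal_set")
}

#' @export
as.matrix.signal_set <- function(x, ...) x$data

#' @export
dim.signal_set <- function(x) dim(x$data)

#' @export
print.signal_set <- function(x, ...) {
  cat("<signal_set> ", nrow(x$data), " signals x ", ncol(x$data), " frames",
      if (!is.null(x$dt)) paste0(", dt = ", x$dt, " s"), "\n", sep = "")
  if (length(x$provenance)) {
    cat("  preprocessing:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

as_signal_set <- function(x, dt = NULL) {
  if (inherits(x, "signal_set")) {
    if (!is.null(dt) && is.null(x$dt)) x$dt <- dt
    return(x)
  }
  signal_set(x, dt = dt)
}

scope_index <- function(scope, T_rec) {
  if (is.null(scope)) return(seq_len(T_rec))
  if (!is.numeric(scope) || length(scope) != 2L) {
    stop_value("scope must be NULL (global) or c(t0, t1)")
  }
  if (scope[1] < 1 || scope[2] > T_rec || scope[1] > scope[2]) {
    stop_value("scope [", scope[1], ", ", scope[2], "] outside recording 1..",
               T_rec)
  }
  seq.int(scope[1], scope[2])
}

## Row-wise z-scoring with sample sd (denominator T - 1), optionally weighted.
## Weights are assumed normalised to sum to length(idx); then the weighted
## squared z-scores sum to T - 1 so that the 1/(T-1)-scaled dyadic sum has a
## unit diagonal.
row_zscore <- function(mat, weights = NULL, what = "signal") {
  T_n <- ncol(mat)
  if (is.null(weights)) {
    mu <- rowMeans(mat)
    ctr <- mat - mu
    s2 <- rowSums(ctr^2) / (T_n - 1)
  } else {
    mu <- as.vector(mat %*% weights) / T_n
    ctr <- mat - mu
    s2 <- as.vector(ctr^2 %*% weights) / (T_n - 1)
  }
  const <- which(s2 <= .Machine$double.eps * T_n)
  if (length(const)) {
    stop_value("constant ", what, " row(s) ", paste(const, collapse = ", "),
               ": z-score undefined")
  }
  ctr / sqrt(s2)
}

#' Z-score signals
#'
#' Each row is centred and scaled to sample standard deviation 1 (denominator
#' `T - 1`) over the chosen scope: the whole recording (the default, as used
#' by the co-fluctuation representation) or a frame window.
#'
#' @param x a [signal_set()] or numeric matrix.
#' @param scope `NULL` for the whole recording, or `c(t0, t1)` frame bounds.
#' @return a `signal_set` with standardised rows (outside the scope, frames
#'   are transformed with the scope's mean and sd).
#' @export
zscore_signals <- function(x, scope = NULL) {
  x <- as_signal_set(x)
  idx <- scope_index(scope, ncol(x$data))
  sub <- x$data[, idx, drop = FALSE]
  mu <- rowMeans(sub)
  s <- apply(sub, 1L, sd)
  const <- which(s <= .Machine$double.eps * length(idx))
  if (length(const)) {
    stop_value("constant signal row(s) ", paste(const, collapse = ", "),
               " over scope [", min(idx), ", ", max(idx), "]")
  }
  x$data <- (x$data - mu) / s
  x$provenance$zscore <- list(scope = if (is.null(scope)) "global" else scope)
  x
}

#' Rank-transform signals
#'
#' Replaces each row by its fractional ranks over the scope (ties get the
#' average rank) and then z-scores the ranks, so that Pearson correlation of
#' the output equals Spearman correlation of the input. This is the signal
#' transformation behind the Spearman variant of the windowed correlation
#' representation.
#'
#' @inheritParams zscore_signals
#' @return a `signal_set` of z-scored ranks.
#' @export
rank_transform <- function(x, scope = NULL) {
  x <- as_signal_set(x)
  idx <- scope_index(scope, ncol(x$data))
  sub <- x$data[, idx, drop = FALSE]
  rk <- t(apply(sub, 1L, rank, ties.method = "average"))
  s <- apply(rk, 1L, sd)
  const <- which(s <= .Machine$double.eps * length(idx))
  if (length(const)) {
    stop_value("constant signal row(s) ", paste(const, collapse = ", "),
               " over scope [", min(idx), ", ", max(idx), "]")
  }
  out <- x
  out$data <- x$data * NA_real_
  out$data[, idx] <- (rk - rowMeans(rk)) / s
  if (!all(seq_len(ncol(x$data)) %in% idx)) {
    ## keep only the transformed scope; ranks outside it are undefined
    out$data <- out$data[, idx, drop = FALSE]
  }
  out$provenance$rank_transform <- list(scope = if (is.null(scope)) "global" else scope)
  out
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass (default order 2) forward and backward
#' (`signal::filtfilt`), giving zero phase distortion. The filter design is
#' recorded in the object's provenance. The start and end of a filtered
#' recording carry edge transients; `trim` drops that many frames from each
#' end (recommended before phase extraction).
#'
#' @param x a [signal_set()] with `dt` set.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < Nyquist`.
#' @param order Butterworth order of the one-way design (default 2).
#' @param trim number of frames to drop at each end after filtering
#'   (default 0).
#' @return a filtered `signal_set`.
#' @export
bandpass <- function(x, low, high, order = 2L, trim = 0L) {
  x <- as_signal_set(x)
  if (is.null(x$dt)) stop_config("bandpass requires the sampling interval dt")
  nyq <- 1 / (2 * x$dt)
  if (!(low > 0 && low < high && high < nyq)) {
    stop_value("band [", low, ", ", high, "] Hz must lie inside (0, ",
               signif(nyq, 4), ") Hz (Nyquist)")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  x$data <- t(apply(x$data, 1L, function(r) signal::filtfilt(bf, r)))
  if (trim > 0L) {
    T_rec <- ncol(x$data)
    if (2L * trim >= T_rec - 1L) stop_value("trim removes the whole recording")
    x$data <- x$data[, (trim + 1L):(T_rec - trim), drop = FALSE]
  }
  x$provenance$bandpass <- list(low = low, high = high, order = order,
                                design = "butterworth zero-phase (filtfilt)",
                                trim = trim)
  x
}

## Analytic signal of a real vector via the frequency-domain Hilbert
## construction (positive frequencies doubled, negative zeroed).
analytic_signal <- function(r) {
  n <- length(r)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  fft(fft(r) * h, inverse = TRUE) / n
}

#' Instantaneous phase container
#'
#' @param theta numeric matrix of phases in radians, wrapped to (-pi, pi].
#' @param source `"hilbert"` or `"wavelet"`.
#' @param band the (low, high) Hz band applied before extraction, or `NULL`.
#' @param dt sampling interval in seconds, if known.
#' @return an object of class `phase_set`.
#' @export
phase_set <- function(theta, source = c("hilbert", "wavelet"), band = NULL,
                      dt = NULL) {
  theta <- as.matrix(theta)
  if (any(!is.finite(theta))) stop_value("phases must be finite")
  theta <- wrap_phase(theta)
  structure(list(theta = theta, source = match.arg(source), band = band,
                 dt = dt),
            class = "phase_set")
}

wrap_phase <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  ## convention: phases live in (-pi, pi]
  out[out == -pi] <- pi
  out
}

#' @export
print.phase_set <- function(x, ...) {
  cat("<phase_set> ", nrow(x$theta), " signals x ", ncol(x$theta),
      " frames (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Instantaneous phases of narrowband signals
#'
#' Extracts per-signal instantaneous phases, either as the argument of the
#' analytic signal (Hilbert construction) or as the argument of the Morlet
#' wavelet coefficient at the band's centre frequency (geometric mean of the
#' edges). If `band` is given the signals are band-pass filtered first;
#' otherwise they are assumed to be narrowband already.
#'
#' @param x a [signal_set()].
#' @param method `"hilbert"` (default) or `"wavelet"`.
#' @param band optional `c(low, high)` Hz band applied before extraction.
#' @param trim frames to drop at each end after filtering (edge transients).
#' @return a [phase_set()].
#' @export
instantaneous_phase <- function(x, method = c("hilbert", "wavelet"),
                                band = NULL, trim = 0L) {
  method <- match.arg(method)
  x <- as_signal_set(x)
  if (!is.null(band)) {
    x <- bandpass(x, band[1], band[2], trim = trim)
  }
  rng <- apply(x$data, 1L, function(r) diff(range(r)))
  const <- which(rng <= .Machine$double.eps * ncol(x$data))
  if (length(const)) {
    stop_value("constant signal row(s) ", paste(const, collapse = ", "),
               ": instantaneous phase undefined")
  }
  if (method == "hilbert") {
    theta <- t(apply(x$data, 1L, function(r) Arg(analytic_signal(r))))
  } else {
    if (is.null(band)) {
      stop_config("wavelet phase extraction needs a band to pick the ",
                  "analysis frequency")
    }
    f0 <- sqrt(band[1] * band[2])
    wf <- wavelet_coefficients(x, f0)
    theta <- Arg(wf$coeffs)
  }
  phase_set(theta, source = method, band = band, dt = x$dt)
}

#' Wavelet coefficient container at a single analysis frequency
#'
#' @param coeffs complex matrix N x T_rec of wavelet coefficients.
#' @param f analysis frequency in Hz.
#' @param dt sampling interval in seconds.
#' @param params list of wavelet metadata (family, bandwidth parameter).
#' @return an object of class `wavelet_frame`.
#' @export
wavelet_frame <- function(coeffs, f, dt = NULL, params = list()) {
  coeffs <- as.matrix(coeffs)
  if (any(!is.finite(Re(coeffs))) || any(!is.finite(Im(coeffs)))) {
    stop_value("wavelet coefficients must be finite")
  }
  structure(list(coeffs = coeffs, f = f, dt = dt, params = params),
            class = "wavelet_frame")
}

#' @export
print.wavelet_frame <- function(x, ...) {
  cat("<wavelet_frame> ", nrow(x$coeffs), " signals x ", ncol(x$coeffs),
      " frames at f = ", x$f, " Hz\n", sep = "")
  invisible(x)
}

#' Continuous Morlet wavelet coefficients at one frequency
#'
#' Computes complex analytic (Morlet) wavelet coefficients of each signal at
#' analysis frequency `f`, by frequency-domain convolution. The wavelet's
#' centre-frequency parameter `omega0` (default 6, the common analytic
#' Morlet) controls the time/frequency bandwidth trade-off and is recorded in
#' the output metadata.
#'
#' @param x a [signal_set()] with `dt` set.
#' @param f analysis frequency in Hz (must be below Nyquist).
#' @param omega0 nondimensional Morlet centre frequency (default 6).
#' @return a [wavelet_frame()].
#' @export
wavelet_coefficients <- function(x, f, omega0 = 6) {
  x <- as_signal_set(x)
  if (is.null(x$dt)) stop_config("wavelet_coefficients requires dt")
  nyq <- 1 / (2 * x$dt)
  if (f >= nyq) {
    stop_value("analysis frequency ", f, " Hz is at or above Nyquist ",
               signif(nyq, 4), " Hz")
  }
  T_rec <- ncol(x$data)
  s <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)  # wavelet scale in seconds
  omega <- 2 * pi * c(seq(0, floor(T_rec / 2)),
                      seq(-ceiling(T_rec / 2) + 1L, -1L)) / (T_rec * x$dt)
  psi_hat <- ifelse(omega > 0,
                    pi^(-0.25) * exp(-(s * omega - omega0)^2 / 2), 0)
  coeffs <- t(apply(x$data, 1L, function(r) fft(fft(r) * psi_hat,
                                                inverse = TRUE) / T_rec))
  wavelet_frame(coeffs, f = f, dt = x$dt,
                params = list(family = "morlet-analytic", omega0 = omega0,
                              scale_s = s))
}
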