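# Dyadic-sum (rank-factor) representation of dynamic connectivity matrices.
#
# Every supported matrix type can be written per frame t as
#   C(t) = scale * sum_i x(i) x(i)^H
# where the x(i) are (transformed) signal vectors in the window around t,
# with any window weights w_i folded in as sqrt(w_i) scalings of the factors.
# The N x N matrix itself is never formed; all downstream computation works
# on the N x k factor matrix of a frame.

DFC_TYPES <- c("correlation", "covariance", "cofluctuation", "ipa",
               "phase_locking", "wavelet_coherence")

#' Sliding-window specification
#'
#' A window of `T` frames centred on the current frame, with nonnegative
#' weights. Odd lengths keep the window symmetric about its centre; even
#' lengths are accepted with a warning and cover one frame more in the past
#' than in the future. `"square"` gives unit weights; `"cosine"` a
#' raised-cosine (Hann-like) taper. Weights are normalised to sum to `T` so
#' that tapered correlation windows keep a unit diagonal.
#'
#' @param T window length in frames (positive integer).
#' @param taper `"square"` (default) or `"cosine"`.
#' @param weights optional explicit nonnegative weights of length `T`
#'   (overrides `taper`).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(T, taper = c("square", "cosine"), weights = NULL) {
  taper <- match.arg(taper)
  T <- as.integer(T)
  if (T < 1L) stop_value("window length must be positive")
  if (T %% 2L == 0L) {
    warning("even window length ", T, ": window is asymmetric about the ",
            "current frame", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- if (taper == "square") rep(1, T) else
      0.5 - 0.5 * cos(2 * pi * seq_len(T) / (T + 1))
  } else {
    taper <- "custom"
  }
  if (length(weights) != T || any(weights < 0) || all(weights == 0)) {
    stop_value("weights must be length T, nonnegative, not all zero")
  }
  weights <- weights * T / sum(weights)
  structure(list(T = T, weights = weights, taper = taper),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("<window_spec> T = ", x$T, " (", x$taper, ")\n", sep = "")
  invisible(x)
}

as_window_spec <- function(window) {
  if (inherits(window, "window_spec")) return(window)
  if (is.numeric(window) && length(window) == 1L) return(window_spec(window))
  stop_value("window must be a window_spec or a single window length")
}

## offsets of window positions relative to the centre frame
window_offsets <- function(T) {
  h_l <- (T - 1L) %/% 2L
  seq.int(-h_l, T - 1L - h_l)
}

#' Rank-factor series for a dynamic connectivity matrix
#'
#' Builds the per-frame dyadic-sum representation of one of the supported
#' dynamic functional connectivity matrix types. Factor matrices are computed
#' lazily per frame with [factor_matrix()]; nothing of size `N x N` is ever
#' stored.
#'
#' Types and their inputs:
#' \describe{
#'   \item{`correlation`}{windowed Pearson (default), Spearman or partial
#'     correlation of a [signal_set()]; factors are within-window z-scored
#'     signals, global scale `1/(T-1)`.}
#'   \item{`covariance`}{windowed sample covariance; factors are
#'     within-window demeaned signals, scale `1/(T-1)`.}
#'   \item{`cofluctuation`}{instantaneous outer product of the globally
#'     z-scored signal vector; one factor per frame, scale 1.}
#'   \item{`ipa`}{instantaneous phase alignment of a [phase_set()]; two
#'     factors per frame, `cos(theta)` and `sin(theta)`; entry `ij` is
#'     `cos(theta_i - theta_j)`.}
#'   \item{`phase_locking`}{Hermitian window average of outer products of
#'     complex phase exponentials of a [phase_set()]; scale `1/T`.}
#'   \item{`wavelet_coherence`}{Hermitian window average of outer products of
#'     unit-modulus-normalised wavelet coefficient vectors of a
#'     [wavelet_frame()]; scale `1/T`.}
#' }
#'
#' The Spearman variant rank-transforms each window before z-scoring. The
#' partial variant maps the window's z-scored signals through the inverse of
#' the windowed correlation matrix, normalised to unit diagonal, so the
#' implied matrix is the sign-normalised precision (its off-diagonal entries
#' are the negatives of the partial correlations); it requires `T - 1 >= N`.
#'
#' @param x a [signal_set()] (correlation, covariance, cofluctuation), a
#'   [phase_set()] (ipa, phase_locking) or a [wavelet_frame()]
#'   (wavelet_coherence). Plain matrices are accepted for signal types.
#' @param type one of `"correlation"`, `"covariance"`, `"cofluctuation"`,
#'   `"ipa"`, `"phase_locking"`, `"wavelet_coherence"`.
#' @param window a [window_spec()] or window length; ignored by the
#'   window-free types (`cofluctuation`, `ipa`).
#' @param variant correlation variant: `"pearson"`, `"spearman"` or
#'   `"partial"`.
#' @return an object of class `dfc_factors`.
#' @export
dfc_factors <- function(x, type = DFC_TYPES, window = NULL,
                        variant = c("pearson", "spearman", "partial")) {
  type <- match.arg(type)
  variant <- match.arg(variant)
  windowed <- type %in% c("correlation", "covariance", "phase_locking",
                          "wavelet_coherence")
  if (windowed) {
    if (is.null(window)) stop_value("type '", type, "' needs a window")
    window <- as_window_spec(window)
  } else {
    window <- window_spec(1L)
  }

  if (type %in% c("correlation", "covariance", "cofluctuation")) {
    x <- as_signal_set(x)
    dat <- x$data
    if (type == "cofluctuation") dat <- zscore_signals(x)$data
  } else if (type %in% c("ipa", "phase_locking")) {
    if (!inherits(x, "phase_set")) {
      stop_value("type '", type, "' needs a phase_set (see ",
                 "instantaneous_phase())")
    }
    dat <- if (type == "ipa") x$theta else exp(1i * x$theta)
  } else {
    if (!inherits(x, "wavelet_frame")) {
      stop_value("wavelet_coherence needs a wavelet_frame")
    }
    m <- Mod(x$coeffs)
    zero <- which(m == 0, arr.ind = TRUE)
    if (nrow(zero)) {
      stop_value("zero-modulus wavelet coefficient at row ", zero[1, 1],
                 ", frame ", zero[1, 2])
    }
    dat <- x$coeffs / m
  }

  N <- nrow(dat)
  T_rec <- ncol(dat)
  T_w <- window$T
  if (windowed && T_w > T_rec) {
    stop_value("window length ", T_w, " exceeds recording length ", T_rec)
  }
  if (type == "correlation" && variant == "partial" && T_w - 1L < N) {
    stop_value("partial correlation needs window T - 1 >= N (got T = ", T_w,
               ", N = ", N, ")")
  }
  off <- window_offsets(T_w)
  valid <- c(1L - min(off), T_rec - max(off))
  scale <- switch(type,
                  correlation = ,
                  covariance = 1 / (T_w - 1),
                  cofluctuation = ,
                  ipa = 1,
                  phase_locking = ,
                  wavelet_coherence = 1 / T_w)
  if (type %in% c("correlation", "covariance") && T_w == 1L) {
    stop_value("windowed ", type, " needs T >= 2")
  }
  structure(list(type = type, variant = if (type == "correlation") variant,
                 data = dat, window = window, scale = scale,
                 valid_range = valid, N = N, T_rec = T_rec,
                 unit_diagonal = type %in% c("correlation", "ipa",
                                             "phase_locking",
                                             "wavelet_coherence"),
                 fixed_trace = type %in% c("correlation", "ipa",
                                           "phase_locking",
                                           "wavelet_coherence"),
                 complex = is.complex(dat)),
            class = "dfc_factors")
}

#' @export
print.dfc_factors <- function(x, ...) {
  cat("<dfc_factors> type = ", x$type,
      if (!is.null(x$variant)) paste0(" (", x$variant, ")"),
      ", N = ", x$N, ", frames ", x$valid_range[1], "..", x$valid_range[2],
      ", window T = ", x$window$T, "\n", sep = "")
  invisible(x)
}

#' Valid frame indices of a factor series
#' @param x a `dfc_factors` object.
#' @return integer vector of frames with a full window.
#' @export
valid_frames <- function(x) seq.int(x$valid_range[1], x$valid_range[2])

check_frame <- function(f, t) {
  if (t < f$valid_range[1] || t > f$valid_range[2]) {
    stop_index("frame ", t, " outside valid range ", f$valid_range[1], "..",
               f$valid_range[2])
  }
}

#' Factor matrix of one frame
#'
#' Returns the `N x k` matrix `X_t` whose (scaled) dyadic sum
#' `scale * X_t X_t^H` is the connectivity matrix at frame `t`. Window
#' weights are already folded in as `sqrt(w_i)` column scalings.
#'
#' @param f a [dfc_factors()] object.
#' @param t frame index (1-based).
#' @return numeric or complex matrix with `k <= T` columns.
#' @export
factor_matrix <- function(f, t) {
  check_frame(f, t)
  T_w <- f$window$T
  sw <- sqrt(f$window$weights)
  cols <- t + window_offsets(T_w)
  switch(f$type,
    cofluctuation = f$data[, t, drop = FALSE],
    ipa = cbind(cos(f$data[, t]), sin(f$data[, t])),
    phase_locking = ,
    wavelet_coherence = sweep(f$data[, cols, drop = FALSE], 2L, sw, "*"),
    covariance = {
      Y <- f$data[, cols, drop = FALSE]
      w <- f$window$weights
      mu <- as.vector(Y %*% w) / T_w
      sweep(Y - mu, 2L, sw, "*")
    },
    correlation = {
      Y <- f$data[, cols, drop = FALSE]
      if (f$variant == "spearman") {
        Y <- t(apply(Y, 1L, rank, ties.method = "average"))
      }
      w <- if (f$window$taper == "square") NULL else f$window$weights
      Z <- tryCatch(row_zscore(Y, w),
                    dfconn_value_error = function(e) {
                      stop_value(conditionMessage(e), " in window of frame ", t)
                    })
      if (f$variant == "partial") {
        R <- tcrossprod(if (is.null(w)) Z else sweep(Z, 2L, w, "*"),
                        Z) * f$scale
        ## precision direction: implied matrix D^-1/2 R^-1 D^-1/2
        Ri <- solve(R)
        d <- sqrt(diag(Ri))
        Z <- (Ri / d) %*% Z
      }
      sweep(Z, 2L, sw, "*")
    })
}

#' Densely reconstruct one frame (testing and small-N use)
#'
#' Materialises `scale * X_t X_t^H`. Intended for oracles and small `N`; a
#' warning is emitted above `warn_n` rows.
#'
#' @param f a [dfc_factors()] object.
#' @param t frame index.
#' @param warn_n warn when `N` exceeds this (default 500).
#' @return symmetric (real types) or Hermitian (complex types) `N x N`
#'   matrix.
#' @export
reconstruct_dense <- function(f, t, warn_n = 500L) {
  if (f$N > warn_n) {
    warning("reconstructing a dense ", f$N, " x ", f$N, " matrix",
            call. = FALSE)
  }
  X <- factor_matrix(f, t)
  C <- f$scale * (X %*% Conj(t(X)))
  (C + Conj(t(C))) / 2
}
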