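# Eigenspace measures: Schatten norms, metastability, distances, Frobenius
# alignment, projector distance, von Neumann entropy, reconfiguration speed
# and the functional connectivity dynamics (FCD) matrix.

norm_from_spectrum <- function(lam, p) {
  if (!length(lam)) stop_value("empty spectrum")
  if (p == 1) sum(abs(lam))
  else if (p == 2) sqrt(sum(lam^2))
  else if (is.infinite(p)) max(abs(lam))
  else stop_value("p must be 1, 2 or Inf")
}

#' Schatten norm of connectivity frames
#'
#' `p = 1` (trace norm): sum of absolute eigenvalues; `p = 2` (Frobenius):
#' square root of the sum of squared eigenvalues, identical to the Euclidean
#' norm of the vectorised matrix; `p = Inf` (spectral): largest absolute
#' eigenvalue. For fixed-trace types (correlation, phase alignment, phase
#' locking) the trace norm is identically `N`; for the rank-1 co-fluctuation
#' frame all three norms coincide with the squared length of the z-scored
#' signal vector.
#'
#' @param x an [evd_frame()] or a fitted [dfc()] object (then a per-frame
#'   series is returned).
#' @param p 1, 2 or `Inf`.
#' @return a scalar, or a numeric vector named by frame for a `dfc` fit.
#' @export
schatten_norm <- function(x, p = 2) UseMethod("schatten_norm")

#' @export
schatten_norm.evd_frame <- function(x, p = 2) norm_from_spectrum(x$values, p)

#' @export
schatten_norm.dfc <- function(x, p = 2) {
  lam <- x$values
  out <- if (p == 1) rowSums(abs(lam))
  else if (p == 2) sqrt(rowSums(lam^2))
  else if (is.infinite(p)) apply(abs(lam), 1L, max)
  else stop_value("p must be 1, 2 or Inf")
  setNames(out, x$frames)
}

#' Norm metastability
#'
#' Standard deviation over time of a Schatten norm of the connectivity
#' matrix; with `p = Inf` this is the spectral metastability. High values
#' mean the recording alternates between strongly and weakly coupled
#' configurations.
#'
#' @param x a fitted [dfc()] object or a numeric norm series.
#' @param p norm index used when `x` is a fit.
#' @return nonnegative scalar (sample standard deviation).
#' @export
metastability <- function(x, p = 2) {
  series <- if (inherits(x, "dfc")) schatten_norm(x, p) else as.numeric(x)
  if (length(series) < 2L) stop_value("metastability needs >= 2 frames")
  sd(series)
}

normalise_frame <- function(fr, p) {
  nrm <- norm_from_spectrum(fr$values, p)
  if (nrm == 0) stop_value("cannot normalise a zero frame")
  fr$values <- fr$values / nrm
  fr
}

#' Schatten distance between two connectivity frames
#'
#' The Schatten-`p` norm of `C_A - C_B`, computed from the signed spectrum
#' of the difference ([difference_spectrum()]) without reconstructing either
#' matrix. With `normalise = TRUE` both frames are first rescaled to unit
#' `p`-norm (the same `p` as the distance). For `p = 2` the identity
#' `d2^2 = |A|^2 + |B|^2 - 2 <A, B>` offers an inner-product route
#' (`method = "inner"`); both routes agree to numerical precision.
#'
#' For two unit-diagonal frames (correlation-like types) the trace-norm
#' distance of the exact matrices is degenerate (the diagonal contributes
#' nothing and the trace of the difference vanishes); a warning is issued
#' and the distance computed anyway.
#'
#' @param A,B [evd_frame()] objects with the same `N`.
#' @param p 1, 2 or `Inf`.
#' @param normalise rescale both frames to unit `p`-norm first.
#' @param method `"spectrum"` (default) or `"inner"` (`p = 2` only).
#' @return nonnegative scalar.
#' @export
dfc_distance <- function(A, B, p = 2, normalise = FALSE,
                         method = c("spectrum", "inner")) {
  method <- match.arg(method)
  if (p == 1 && isTRUE(A$unit_diagonal) && isTRUE(B$unit_diagonal)) {
    warning("trace-norm distance between unit-diagonal matrices is ",
            "degenerate; consider p = 2 or Inf", call. = FALSE)
  }
  if (normalise) {
    A <- normalise_frame(A, p)
    B <- normalise_frame(B, p)
  }
  if (method == "inner") {
    if (p != 2) stop_value("the inner-product route exists only for p = 2")
    d2 <- sum(A$values^2) + sum(B$values^2) - 2 * frobenius_inner(A, B)
    return(sqrt(max(d2, 0)))
  }
  norm_from_spectrum(difference_spectrum(A, B), p)
}

#' Frobenius inner product of two connectivity frames
#'
#' `Tr(C_A^H C_B)`, computed in eigenspace as
#' `sum_ij lambda_i mu_j |u_i^H v_j|^2` -- an `r_A x r_B` computation instead
#' of an `N x N` one.
#'
#' @param A,B [evd_frame()] objects with the same `N`.
#' @return real scalar.
#' @export
frobenius_inner <- function(A, B) {
  if (A$N != B$N) stop_value("dimension mismatch: ", A$N, " vs ", B$N)
  M <- Conj(t(A$vectors)) %*% B$vectors
  as.numeric(A$values %*% Mod(M)^2 %*% B$values)
}

#' Cosine alignment of two connectivity frames
#'
#' `<A, B> / (|A|_2 |B|_2)`; lies in `[0, 1]` for positive-semidefinite
#' frames and equals the cosine similarity of the vectorised dense matrices.
#'
#' @inheritParams frobenius_inner
#' @return scalar in `[-1, 1]`.
#' @export
cosine_alignment <- function(A, B) {
  na <- norm_from_spectrum(A$values, 2)
  nb <- norm_from_spectrum(B$values, 2)
  if (na == 0 || nb == 0) stop_value("cosine alignment of a zero frame")
  max(min(frobenius_inner(A, B) / (na * nb), 1), -1)
}

#' Projector (subspace) distance between two frames
#'
#' Frobenius distance between the rank-`r` spectral projectors of two
#' frames, `|P_A - P_B|_F = sqrt(2r - 2 sum_ij |u_i^H v_j|^2)` over the
#' top-`r` eigenvectors of each: an eigenvalue-free comparison of the
#' dominant subspaces.
#'
#' @inheritParams frobenius_inner
#' @param r subspace dimension; at most the retained rank of both frames.
#' @return nonnegative scalar (`sqrt(2) * sqrt(r)` for orthogonal
#'   subspaces).
#' @export
projector_distance <- function(A, B, r = 1L) {
  if (A$N != B$N) stop_value("dimension mismatch: ", A$N, " vs ", B$N)
  if (r > length(A$values) || r > length(B$values)) {
    stop_value("r = ", r, " exceeds the retained rank of a frame")
  }
  M <- Conj(t(A$vectors[, seq_len(r), drop = FALSE])) %*%
    B$vectors[, seq_len(r), drop = FALSE]
  sqrt(max(2 * r - 2 * sum(Mod(M)^2), 0))
}

#' Von Neumann entropy of a connectivity frame
#'
#' Shannon entropy of the eigenvalue spectrum normalised to sum 1:
#' `E = -sum lambda~ log(lambda~)` with the convention `0 log 0 = 0`.
#' Zero for a rank-1 frame, `log(k)` for a uniform spectrum over `k`
#' eigenvalues; measures how many axes of variation the signals explore.
#' Defined for positive-semidefinite spectra only. When a window taper is
#' active the spectrum is shaped by the weights and the entropy should be
#' interpreted with care (a warning is issued).
#'
#' @param x an [evd_frame()] or fitted [dfc()] object.
#' @param base logarithm base (default natural log; use 2 for bits).
#' @return nonnegative scalar, or per-frame vector for a fit.
#' @export
von_neumann_entropy <- function(x, base = exp(1)) {
  UseMethod("von_neumann_entropy")
}

entropy_from_values <- function(lam, base, tol = 1e-8) {
  mx <- max(abs(lam), 0)
  if (mx == 0 || !length(lam)) stop_value("entropy of an empty spectrum")
  if (min(lam) < -tol * mx) {
    stop_value("entropy defined for PSD spectra only (found eigenvalue ",
               signif(min(lam), 4), ")")
  }
  lam <- lam[lam > 0]
  lt <- lam / sum(lam)
  -sum(lt * log(lt)) / log(base)
}

#' @export
von_neumann_entropy.evd_frame <- function(x, base = exp(1)) {
  if (isTRUE(x$tapered)) {
    warning("window taper shapes the eigenvalue spectrum; interpret the ",
            "entropy with care", call. = FALSE)
  }
  entropy_from_values(x$values, base)
}

#' @export
von_neumann_entropy.dfc <- function(x, base = exp(1)) {
  if (isTRUE(x$tapered)) {
    warning("window taper shapes the eigenvalue spectrum; interpret the ",
            "entropy with care", call. = FALSE)
  }
  out <- vapply(seq_along(x$frames), function(i)
    entropy_from_values(x$values[i, seq_len(x$rank[i])], base), numeric(1))
  setNames(out, x$frames)
}

#' Reconfiguration speed
#'
#' The distance between the connectivity matrix at frame `t` and at frame
#' `t - tau`: `s(t) = d_p(C(t), C(t - tau))`. Peaks mark transitions
#' between connectivity regimes.
#'
#' @param object a fitted [dfc()] object.
#' @param tau delay in frames (>= 1, < number of fitted frames).
#' @param p Schatten index of the distance.
#' @param normalise rescale frames to unit `p`-norm before the distance.
#' @return numeric vector of length `n_frames - tau`, named by the frame
#'   `t` of each comparison.
#' @export
reconfiguration_speed <- function(object, tau = 1L, p = 2, normalise = FALSE) {
  n <- length(object$frames)
  if (tau < 1L || tau >= n) {
    stop_value("tau must be in 1..", n - 1L, " (got ", tau, ")")
  }
  idx <- seq.int(tau + 1L, n)
  out <- vapply(idx, function(i) {
    dfc_distance(dfc_frame(object, object$frames[i]),
                 dfc_frame(object, object$frames[i - tau]),
                 p = p, normalise = normalise)
  }, numeric(1))
  setNames(out, object$frames[idx])
}

#' Functional connectivity dynamics (FCD) matrix
#'
#' The symmetric frame-by-frame distance matrix
#' `FCD_ij = d_p(C(t_i), C(t_j))` over (possibly strided) fitted frames: a
#' condensed portrait of how connectivity evolves across the recording.
#' For `p = 2` it is computed from precomputed frame norms plus pairwise
#' Frobenius inner products (no per-pair difference spectra).
#'
#' @inheritParams reconfiguration_speed
#' @param stride keep every `stride`-th frame (>= 1).
#' @param max_entries guard against accidentally huge matrices (default
#'   2e8 entries); increase the stride rather than this cap.
#' @return an `n x n` matrix of class `fcd_matrix` with the frame indices
#'   as dimnames and `p`, `normalise`, `stride` attributes.
#' @export
fcd_matrix <- function(object, p = 2, normalise = FALSE, stride = 1L,
                       max_entries = 2e8) {
  if (stride < 1L) stop_value("stride must be >= 1")
  keep <- seq.int(1L, length(object$frames), by = stride)
  n <- length(keep)
  if (as.double(n)^2 > max_entries) {
    stop_value("FCD would have ", n, "^2 entries; increase the stride")
  }
  frames <- object$frames[keep]
  fr <- lapply(frames, function(t) {
    f <- dfc_frame(object, t)
    if (normalise) f <- normalise_frame(f, p) else f
  })
  D <- matrix(0, n, n, dimnames = list(frames, frames))
  if (p == 2) {
    sq <- vapply(fr, function(f) sum(f$values^2), numeric(1))
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d2 <- sq[i] + sq[j] - 2 * frobenius_inner(fr[[i]], fr[[j]])
        D[i, j] <- D[j, i] <- sqrt(max(d2, 0))
      }
    }
  } else {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        D[i, j] <- D[j, i] <-
          norm_from_spectrum(difference_spectrum(fr[[i]], fr[[j]]), p)
      }
    }
  }
  structure(D, class = c("fcd_matrix", "matrix", "array"), p = p,
            normalise = normalise, stride = stride)
}

#' @export
print.fcd_matrix <- function(x, ...) {
  cat("<fcd_matrix> ", nrow(x), " x ", ncol(x), " frames, p = ",
      format(attr(x, "p")), if (attr(x, "normalise")) ", normalised",
      "\n", sep = "")
  invisible(x)
}

## ---- entry time-course similarity between matrix types ---------------------

running_sum <- function(x, T_w) {
  cs <- cumsum(c(0, x))
  cs[(T_w + 1L):length(cs)] - cs[1:(length(cs) - T_w)]
}

## time course of entry (i, j) of a given matrix type; returns the series on
## the type's valid frames together with those frame indices
entry_timecourse <- function(type, dat, i, j, T_w) {
  T_rec <- ncol(dat)
  if (type %in% c("cofluctuation", "ipa")) {
    series <- if (type == "cofluctuation") dat[i, ] * dat[j, ] else
      cos(dat[i, ] - dat[j, ])
    return(list(frames = seq_len(T_rec), values = series))
  }
  off <- window_offsets(T_w)
  frames <- seq.int(1L - min(off), T_rec - max(off))
  xi <- dat[i, ]; xj <- dat[j, ]
  sx <- running_sum(xi, T_w); sy <- running_sum(xj, T_w)
  sxx <- running_sum(xi^2, T_w); syy <- running_sum(xj^2, T_w)
  sxy <- running_sum(xi * xj, T_w)
  cov_w <- (sxy - sx * sy / T_w) / (T_w - 1)
  if (type == "covariance") return(list(frames = frames, values = cov_w))
  vx <- (sxx - sx^2 / T_w) / (T_w - 1)
  vy <- (syy - sy^2 / T_w) / (T_w - 1)
  list(frames = frames, values = cov_w / sqrt(vx * vy))
}

#' Similarity of two matrix types' entry time courses across window sizes
#'
#' For sampled signal pairs `(i, j)`, computes the Pearson correlation in
#' time between the `(i, j)` entry of matrix type `type_a` and of `type_b`,
#' averaged over pairs, for every window size in `windows` (the window
#' applies to whichever type is windowed). This reproduces the standard
#' diagnostic for choosing a matrix type: phase alignment matches the
#' windowed correlation best at a band-dependent window size, and the
#' co-fluctuation matches the windowed covariance best as the window shrinks
#' towards 1.
#'
#' @param x a [signal_set()] or matrix.
#' @param type_a,type_b matrix types to compare (`"correlation"`,
#'   `"covariance"`, `"cofluctuation"`, `"ipa"`).
#' @param windows vector of window lengths (odd values recommended).
#' @param band `c(low, high)` Hz band; required when either type is
#'   `"ipa"`, in which case both types are computed on the band-passed
#'   signals.
#' @param n_pairs number of random signal pairs to average over.
#' @param seed optional seed for the pair sampling.
#' @return data frame with columns `window` and `similarity`.
#' @export
matrix_timecourse_similarity <- function(x, type_a, type_b, windows,
                                         band = NULL, n_pairs = 10L,
                                         seed = NULL) {
  x <- as_signal_set(x)
  types <- c(type_a, type_b)
  if (!all(types %in% c("correlation", "covariance", "cofluctuation",
                        "ipa"))) {
    stop_value("supported types: correlation, covariance, cofluctuation, ipa")
  }
  if ("ipa" %in% types) {
    if (is.null(band)) stop_config("comparing against ipa requires a band")
    x <- bandpass(x, band[1], band[2])
  }
  dat <- list()
  for (ty in unique(types)) {
    dat[[ty]] <- switch(ty,
      ipa = instantaneous_phase(x, method = "hilbert")$theta,
      cofluctuation = zscore_signals(x)$data,
      x$data)
  }
  N <- nrow(x$data)
  if (N < 2L) stop_value("need at least 2 signals")
  if (!is.null(seed)) set.seed(seed)
  pairs <- t(replicate(n_pairs, sample.int(N, 2L)))
  if (max(windows) + 1L >= ncol(x$data)) {
    stop_value("largest window leaves fewer than 2 valid frames")
  }
  sim <- vapply(windows, function(T_w) {
    r <- vapply(seq_len(nrow(pairs)), function(k) {
      a <- entry_timecourse(type_a, dat[[type_a]], pairs[k, 1], pairs[k, 2],
                            T_w)
      b <- entry_timecourse(type_b, dat[[type_b]], pairs[k, 1], pairs[k, 2],
                            T_w)
      common <- intersect(a$frames, b$frames)
      cor(a$values[match(common, a$frames)],
          b$values[match(common, b$frames)])
    }, numeric(1))
    mean(r)
  }, numeric(1))
  data.frame(window = windows, similarity = sim)
}
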