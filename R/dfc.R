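# The main fitting function: signals in, eigen-represented dynamic
# connectivity series out, plus the usual S3 methods.

#' Fit a dynamic functional connectivity model
#'
#' Builds the chosen dynamic connectivity representation of a multivariate
#' recording and eigendecomposes every frame through its temporal Gram
#' matrix ([tcevd_frame()]), returning the full series of eigenvalues and
#' eigenvectors. This is lossless: with the default `n_eigs` every
#' eigenvalue above the structural-rank tolerance is kept, and
#' `U diag(lambda) U^H` reproduces the frame's connectivity matrix. All
#' downstream measures ([schatten_norm()], [dfc_distance()],
#' [von_neumann_entropy()], [reconfiguration_speed()], [fcd_matrix()], ...)
#' operate on this object without ever forming an `N x N` matrix.
#'
#' Phase-based types (`ipa`, `phase_locking`) accept either a [phase_set()]
#' or raw signals plus a `band`, in which case phases are extracted with the
#' analytic-signal (Hilbert) construction after band-pass filtering.
#' `wavelet_coherence` accepts a [wavelet_frame()] or raw signals plus `f`.
#'
#' @param x a [signal_set()] or numeric matrix (rows = signals), or a
#'   [phase_set()] / [wavelet_frame()] for the phase/wavelet types.
#' @param type connectivity matrix type; see [dfc_factors()].
#' @param window window length in frames or a [window_spec()] (windowed
#'   types only).
#' @param variant correlation variant (`"pearson"`, `"spearman"`,
#'   `"partial"`).
#' @param band `c(low, high)` Hz band for phase extraction from raw signals.
#' @param f analysis frequency in Hz for `wavelet_coherence` from raw
#'   signals.
#' @param dt sampling interval in seconds (needed when `band` or `f` is
#'   used with a plain matrix).
#' @param n_eigs number of eigenpairs to retain per frame (`NULL` =
#'   lossless, i.e. all above tolerance). Truncation is a denoising choice.
#' @param tol relative null-eigenvalue tolerance (default 1e-10).
#' @param trim frames to drop at each end after filtering, for phase types
#'   fed with raw signals (edge transients of the filter and analytic
#'   signal).
#' @param verbose log progress messages.
#' @return an object of class `dfc` with components `values` (frames x r
#'   eigenvalue matrix, padded with zeros past each frame's rank),
#'   `vectors` (N x r x frames array), `rank` (per-frame retained count),
#'   `frames` (frame indices), and metadata.
#' @examples
#' bench <- planted_covariance_signals(N = 6, n_states = 2, chunk_len = 150,
#'                                     seed = 1)
#' fit <- dfc(bench$signals, type = "covariance", window = 21)
#' fit
#' summary(fit)
#' @export
dfc <- function(x, type = DFC_TYPES, window = NULL,
                variant = c("pearson", "spearman", "partial"), band = NULL,
                f = NULL, dt = NULL, n_eigs = NULL, tol = 1e-10, trim = 0L,
                verbose = FALSE) {
  cl <- match.call()
  type <- match.arg(type)
  variant <- match.arg(variant)
  if (type %in% c("ipa", "phase_locking") && !inherits(x, "phase_set")) {
    x <- instantaneous_phase(as_signal_set(x, dt = dt), method = "hilbert",
                             band = band, trim = trim)
  }
  if (type == "wavelet_coherence" && !inherits(x, "wavelet_frame")) {
    if (is.null(f)) stop_value("wavelet_coherence from raw signals needs f")
    x <- wavelet_coefficients(as_signal_set(x, dt = dt), f)
  }
  fac <- dfc_factors(x, type = type, window = window, variant = variant)
  log_msg("INFO", "factors", paste0("type=", type, " N=", fac$N, " frames=",
                                    fac$valid_range[1], "..",
                                    fac$valid_range[2]), verbose)
  fit <- evd_series(fac, n_eigs = n_eigs, tol = tol, verbose = verbose)
  fit$call <- cl
  fit
}

#' Eigendecompose every valid frame of a factor series
#'
#' Runs [tcevd_frame()] over all frames with a full window, using the
#' closed-form paths where they exist (rank-1 co-fluctuation, rank-2 phase
#' alignment). Output is deterministic for fixed input.
#'
#' @param fac a [dfc_factors()] object.
#' @inheritParams dfc
#' @return a `dfc` object.
#' @export
evd_series <- function(fac, n_eigs = NULL, tol = 1e-10, verbose = FALSE) {
  frames <- valid_frames(fac)
  n_frames <- length(frames)
  k_t <- switch(fac$type, cofluctuation = 1L, ipa = 2L, fac$window$T)
  if (!is.null(n_eigs) && n_eigs > k_t) {
    stop_value("requested eigenvectors (", n_eigs, ") exceed window rank (",
               k_t, ")")
  }
  r_max <- min(k_t, fac$N, n_eigs %||% .Machine$integer.max)
  if (k_t > fac$N && fac$type != "cofluctuation") {
    log_msg("INFO", "evd", paste0("window rank ", k_t, " exceeds N = ",
                                  fac$N,
                                  ": using the dense path per frame"),
            verbose)
  }
  vals <- matrix(0, n_frames, r_max)
  vecs <- array(if (fac$complex) 0i else 0, c(fac$N, r_max, n_frames))
  rank_est <- integer(n_frames)
  for (i in seq_len(n_frames)) {
    t <- frames[i]
    fr <- if (fac$type == "cofluctuation") {
      z <- fac$data[, t]
      nz <- sqrt(sum(z^2))
      evd_frame(nz^2, fix_signs(matrix(z / nz, ncol = 1L)), frame = t,
                matrix_type = "cofluctuation", k = 1L)
    } else if (fac$type == "ipa") {
      ipa_evd_analytic(cos(fac$data[, t]), sin(fac$data[, t]), frame = t,
                       tol = tol)
    } else {
      tcevd_frame(fac, t, n_eigs = n_eigs, tol = tol)
    }
    r <- min(length(fr$values), r_max)
    rank_est[i] <- r
    if (r) {
      vals[i, seq_len(r)] <- fr$values[seq_len(r)]
      vecs[, seq_len(r), i] <- fr$vectors[, seq_len(r)]
    }
    if (verbose && i %% 1000L == 0L) {
      log_msg("INFO", "evd", paste0(i, "/", n_frames, " frames"), verbose)
    }
  }
  structure(list(values = vals, vectors = vecs, rank = rank_est,
                 frames = frames, type = fac$type, variant = fac$variant,
                 window = fac$window, scale = fac$scale, N = fac$N,
                 T_rec = fac$T_rec, n_eigs = n_eigs, tol = tol,
                 unit_diagonal = fac$unit_diagonal,
                 fixed_trace = fac$fixed_trace,
                 tapered = fac$window$taper != "square", call = NULL),
            class = "dfc")
}

#' Extract one frame of a fitted dfc object
#'
#' @param object a [dfc()] fit.
#' @param t absolute frame index (must be one of `object$frames`).
#' @return an [evd_frame()].
#' @export
dfc_frame <- function(object, t) {
  i <- match(t, object$frames)
  if (is.na(i)) {
    stop_index("frame ", t, " not in the fitted range ",
               min(object$frames), "..", max(object$frames))
  }
  r <- object$rank[i]
  U <- object$vectors[, seq_len(r), i, drop = FALSE]
  dim(U) <- dim(U)[1:2]
  evd_frame(object$values[i, seq_len(r)], U,
            frame = t, matrix_type = object$type, k = object$window$T,
            unit_diagonal = object$unit_diagonal, tapered = object$tapered)
}

#' Densely reconstruct one fitted frame
#'
#' @inheritParams dfc_frame
#' @return `N x N` symmetric/Hermitian matrix `U diag(lambda) U^H`.
#' @export
dense_frame <- function(object, t) {
  fr <- dfc_frame(object, t)
  C <- fr$vectors %*% (fr$values * Conj(t(fr$vectors)))
  (C + Conj(t(C))) / 2
}

#' @export
print.dfc <- function(x, ...) {
  cat("Dynamic functional connectivity fit (", x$type,
      if (!is.null(x$variant)) paste0(", ", x$variant), ")\n", sep = "")
  cat("  signals:", x$N, " frames:", length(x$frames),
      sprintf("(%d..%d of %d)", min(x$frames), max(x$frames), x$T_rec), "\n")
  if (x$window$T > 1L) {
    cat("  window: T =", x$window$T, paste0("(", x$window$taper, ")"), "\n")
  }
  cat("  retained eigenpairs per frame:",
      if (min(x$rank) == max(x$rank)) max(x$rank) else
        paste0(min(x$rank), "-", max(x$rank)), "\n")
  invisible(x)
}

#' @export
summary.dfc <- function(object, ...) {
  norms <- vapply(c(1, 2, Inf), function(p)
    mean(schatten_norm(object, p)), numeric(1))
  meta <- vapply(c(1, 2, Inf), function(p)
    metastability(object, p), numeric(1))
  ent <- von_neumann_entropy(object)
  out <- list(type = object$type, N = object$N,
              n_frames = length(object$frames),
              window = object$window$T,
              mean_norms = setNames(norms, c("p1", "p2", "pinf")),
              metastability = setNames(meta, c("p1", "p2", "pinf")),
              entropy = c(mean = mean(ent), sd = sd(ent)),
              rank = range(object$rank))
  class(out) <- "summary.dfc"
  out
}

#' @export
print.summary.dfc <- function(x, ...) {
  cat("Dynamic connectivity summary (", x$type, ")\n", sep = "")
  cat("  N =", x$N, ", frames =", x$n_frames, ", window T =", x$window, "\n")
  cat("  mean norms      p=1:", signif(x$mean_norms[1], 5),
      " p=2:", signif(x$mean_norms[2], 5),
      " p=Inf:", signif(x$mean_norms[3], 5), "\n")
  cat("  metastability   p=1:", signif(x$metastability[1], 5),
      " p=2:", signif(x$metastability[2], 5),
      " p=Inf:", signif(x$metastability[3], 5), "\n")
  cat("  von Neumann entropy:", signif(x$entropy[1], 5), "+/-",
      signif(x$entropy[2], 5), "\n")
  cat("  retained rank:", x$rank[1], "-", x$rank[2], "\n")
  invisible(x)
}

#' @export
coef.dfc <- function(object, ...) {
  out <- object$values
  rownames(out) <- object$frames
  colnames(out) <- paste0("lambda", seq_len(ncol(out)))
  out
}

#' Plot method: norm and entropy time courses
#'
#' @param x a [dfc()] fit.
#' @param p Schatten norm index for the top panel.
#' @param ... passed to [plot()].
#' @export
plot.dfc <- function(x, p = 2, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  nrm <- schatten_norm(x, p)
  plot(x$frames, nrm, type = "l", xlab = "frame",
       ylab = sprintf("Schatten-%s norm", format(p)),
       main = paste("dynamic connectivity:", x$type), ...)
  ent <- von_neumann_entropy(x)
  plot(x$frames, ent, type = "l", xlab = "frame",
       ylab = "von Neumann entropy", ...)
  invisible(x)
}
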