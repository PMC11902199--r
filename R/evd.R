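# Per-frame eigendecomposition through the temporal Gram matrix, the
# analytic rank-2 phase-alignment path, and spectra of differences of
# eigen-represented matrices.

#' Eigendecomposition of one connectivity frame
#'
#' Container for the retained eigenpairs of one dynamic connectivity matrix
#' `C(t) = U diag(lambda) U^H`: eigenvalues in descending order, orthonormal
#' eigenvector columns (real for real matrix types), and the count of
#' eigenvalues above the relative null tolerance.
#'
#' @param values numeric eigenvalues, descending.
#' @param vectors `N x r` matrix of eigenvectors (columns).
#' @param frame frame index.
#' @param matrix_type matrix type tag.
#' @param k number of factors the frame was built from.
#' @param unit_diagonal does the implied matrix have a unit diagonal?
#' @param tapered was a non-square window taper active?
#' @return an object of class `evd_frame`.
#' @export
evd_frame <- function(values, vectors, frame = NA_integer_,
                      matrix_type = "custom", k = length(values),
                      unit_diagonal = FALSE, tapered = FALSE) {
  structure(list(values = as.numeric(values), vectors = vectors,
                 rank_estimate = length(values), frame = frame,
                 matrix_type = matrix_type, N = nrow(vectors), k = k,
                 unit_diagonal = unit_diagonal, tapered = tapered),
            class = "evd_frame")
}

#' @export
print.evd_frame <- function(x, ...) {
  cat("<evd_frame> frame ", x$frame, " (", x$matrix_type, "), N = ", x$N,
      ", rank ", x$rank_estimate, "\n", sep = "")
  cat("  eigenvalues:", paste(signif(head(x$values, 6L), 4), collapse = ", "),
      if (length(x$values) > 6L) "...", "\n")
  invisible(x)
}

## Deterministic eigenvector orientation: the entry of largest modulus is
## made (real) positive; ties broken by lowest index. All measures are
## invariant to this, it only pins down serialisation and cross-run
## comparisons.
fix_signs <- function(U) {
  if (!ncol(U)) return(U)
  for (j in seq_len(ncol(U))) {
    i <- which.max(Mod(U[, j]))
    piv <- U[i, j]
    if (piv != 0) {
      U[, j] <- if (is.complex(U)) U[, j] * Conj(piv) / Mod(piv) else
        U[, j] * sign(Re(piv))
    }
  }
  U
}

#' Eigendecomposition of a frame via its temporal Gram matrix
#'
#' Computes the nonzero eigenvalues and eigenvectors of
#' `C(t) = scale * X X^H` from the small `k x k` Gram matrix `R = X^H X` of
#' the frame's factor vectors: the eigenvalues of `C(t)` are `scale` times
#' those of `R`, and each eigenvector of `C(t)` is the corresponding linear
#' combination of the factors, normalised. Cost is `O(N k^2 + k^3)` and no
#' `N x N` matrix is formed. When the factor count exceeds `N` the matrix is
#' full-rank and the Gram route has no advantage, so the frame is
#' reconstructed densely and decomposed directly (a message notes the
#' switch).
#'
#' Eigenvalues are retained while they exceed `tol` times the largest
#' (structural-rank tolerance) and, if `n_eigs` is given, at most `n_eigs`
#' of them.
#'
#' @param f a [dfc_factors()] object.
#' @param t frame index.
#' @param n_eigs optional cap on retained eigenpairs (truncation/denoising);
#'   must not exceed the frame's factor count.
#' @param tol relative null tolerance (default 1e-10).
#' @param dense_switch set `FALSE` to force the Gram route even when
#'   `k > N`.
#' @return an [evd_frame()].
#' @export
tcevd_frame <- function(f, t, n_eigs = NULL, tol = 1e-10,
                        dense_switch = TRUE) {
  X <- factor_matrix(f, t)
  k <- ncol(X)
  if (!is.null(n_eigs) && n_eigs > k) {
    stop_value("requested eigenvectors (", n_eigs, ") exceed window rank (",
               k, ")")
  }
  n_cap <- if (is.null(n_eigs)) -1L else as.integer(n_eigs)
  if (any(!is.finite(Re(X)))) stop_value("non-finite factors at frame ", t)
  if (!is.complex(X)) {
    if (dense_switch && k > f$N) {
      C <- f$scale * tcrossprod(X)
      res <- cpp_dense_evd(C, tol, n_cap)
    } else {
      res <- cpp_gram_evd(X, f$scale, tol, n_cap)
    }
    vals <- res$values
    U <- fix_signs(res$vectors)
  } else {
    if (dense_switch && k > f$N) {
      C <- f$scale * (X %*% Conj(t(X)))
      e <- eigen((C + Conj(t(C))) / 2, symmetric = TRUE)
      keep <- which(e$values > tol * max(abs(e$values[1]), 0))
      if (!is.null(n_eigs)) keep <- head(keep, n_eigs)
      vals <- e$values[keep]
      U <- fix_signs(e$vectors[, keep, drop = FALSE])
    } else {
      R <- Conj(t(X)) %*% X
      e <- eigen((R + Conj(t(R))) / 2, symmetric = TRUE)
      mx <- max(abs(e$values[1]), 0)
      keep <- which(e$values > tol * mx)
      if (!is.null(n_eigs)) keep <- head(keep, n_eigs)
      vals <- f$scale * e$values[keep]
      U <- X %*% e$vectors[, keep, drop = FALSE]
      nrms <- sqrt(colSums(Mod(U)^2))
      U <- sweep(U, 2L, pmax(nrms, .Machine$double.xmin), "/")
      U <- fix_signs(U)
    }
  }
  evd_frame(vals, U, frame = t, matrix_type = f$type, k = k,
            unit_diagonal = f$unit_diagonal,
            tapered = f$window$taper != "square")
}

#' Closed-form eigendecomposition of a phase-alignment frame
#'
#' The instantaneous phase alignment matrix `cc^T + ss^T` has rank at most 2,
#' so its 2 x 2 Gram matrix is solved in closed form (quadratic
#' characteristic polynomial) rather than numerically. When the sine vector
#' is parallel to the cosine vector (all phases equal or antipodal) the rank
#' collapses to 1 and a single eigenpair is returned.
#'
#' @param c,s numeric vectors: elementwise cosine and sine of the phases.
#' @param frame frame index tag.
#' @param tol relative null tolerance.
#' @return an [evd_frame()] with `lambda_1 + lambda_2 = N`.
#' @export
ipa_evd_analytic <- function(c, s, frame = NA_integer_, tol = 1e-10) {
  a <- sum(c * c); b <- sum(c * s); d <- sum(s * s)
  tr <- a + d
  disc <- sqrt(max((a - d)^2 / 4 + b^2, 0))
  lam <- c(tr / 2 + disc, tr / 2 - disc)
  ## Gram eigenvectors (v1, v2) of [[a, b], [b, d]]
  U <- matrix(0, length(c), 2L)
  vals <- numeric(0)
  for (j in 1:2) {
    if (lam[j] <= tol * lam[1]) next
    v <- if (abs(b) > .Machine$double.eps * max(a, d, 1)) {
      c(b, lam[j] - a)
    } else if ((j == 1L) == (a >= d)) c(1, 0) else c(0, 1)
    u <- c * v[1] + s * v[2]
    nrm <- sqrt(sum(u^2))
    if (nrm == 0) next
    U[, length(vals) + 1L] <- u / nrm
    vals <- c(vals, lam[j])
  }
  U <- fix_signs(U[, seq_along(vals), drop = FALSE])
  evd_frame(vals, U, frame = frame, matrix_type = "ipa", k = 2L,
            unit_diagonal = TRUE)
}

#' Signed spectrum of a difference of eigen-represented matrices
#'
#' Computes the nonzero eigenvalues of `C_A - C_B` without reconstructing
#' either matrix. Stack the scaled eigenvectors
#' `F = [sqrt(lambda_A) U_A, sqrt(lambda_B) U_B]` with a sign matrix
#' `D = diag(+1, ..., -1, ...)`; the nonzero eigenvalues of `C_A - C_B`
#' coincide with those of the small `(r_A + r_B)` operator product
#' `D (F^H F)`, which are real. Numerically the difference is compressed
#' onto an orthonormal basis of `span(U_A, U_B)` -- obtained from the
#' eigendecomposition of the small Gram matrix of the stacked eigenvectors
#' -- and the resulting Hermitian matrix is decomposed, so the spectrum is
#' exactly real and identical frames cancel to rounding error.
#'
#' @param A,B [evd_frame()] objects over the same `N` signals, both from the
#'   same (real or complex) matrix family.
#' @return numeric eigenvalues sorted by decreasing absolute value.
#' @export
difference_spectrum <- function(A, B) {
  if (A$N != B$N) {
    stop_value("frames have different dimension: ", A$N, " vs ", B$N)
  }
  if (is.complex(A$vectors) != is.complex(B$vectors)) {
    stop_value("cannot mix real and complex matrix families")
  }
  if (any(A$values < 0) || any(B$values < 0)) {
    stop_value("difference_spectrum expects PSD frames")
  }
  r_a <- length(A$values)
  Y <- cbind(A$vectors, B$vectors)
  G <- Conj(t(Y)) %*% Y
  eg <- eigen((G + Conj(t(G))) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-12 * max(eg$values)
  ## coefficients of an orthonormal basis Q = Y %*% W of span(U_A, U_B)
  W <- sweep(eg$vectors[, keep, drop = FALSE], 2L,
             sqrt(eg$values[keep]), "/")
  R_a <- Conj(t(W)) %*% G[, seq_len(r_a), drop = FALSE]
  R_b <- Conj(t(W)) %*% G[, r_a + seq_len(length(B$values)), drop = FALSE]
  M <- R_a %*% (A$values * Conj(t(R_a))) -
    R_b %*% (B$values * Conj(t(R_b)))
  ev <- eigen((M + Conj(t(M))) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  ev[order(abs(ev), decreasing = TRUE)]
}
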