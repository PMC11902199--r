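# Empirical cost-scaling measurement: Gram-matrix route versus dense
# eigendecomposition as the signal count N grows at fixed window length.

#' Measure eigendecomposition cost scaling in N
#'
#' Times the per-frame eigendecomposition of a windowed covariance matrix of
#' `N` i.i.d. Gaussian signals with window length `T`, for each `N` in
#' `N_grid`, via (a) the Gram-matrix route (cost `O(N T^2 + T^3)`, linear in
#' `N` at fixed `T`) and (b) the dense route (build the `N x N` matrix and
#' eigendecompose it, superquadratic in `N`). Kernels are timed in compiled
#' code over enough repetitions to swamp timer resolution.
#'
#' @param N_grid signal counts to test (gram route).
#' @param N_grid_dense signal counts for the dense route (defaults to the
#'   part of `N_grid` not above 2000, to keep runtime and memory sane).
#' @param T window length (default 10).
#' @param reps repetitions per measurement (default 3; the minimum time is
#'   kept).
#' @param min_time target accumulated time per measurement in seconds; the
#'   kernel is looped enough times to reach it.
#' @param seed seed for the random factor matrices.
#' @return data frame with columns `method`, `N`, `seconds` (per call).
#' @export
benchmark_evd_scaling <- function(N_grid = round(10^seq(2, 4, by = 0.5)),
                                  N_grid_dense = NULL,
                                  T = 10L, reps = 3L, min_time = 0.05,
                                  seed = 1L) {
  if (is.null(N_grid_dense)) N_grid_dense <- N_grid[N_grid <= 2000]
  set.seed(seed)
  time_method <- function(N, fun) {
    X <- matrix(rnorm(N * T), N, T)
    X <- X - rowMeans(X)
    scale <- 1 / (T - 1)
    n_loop <- 1L
    repeat {
      el <- fun(X, scale, n_loop)
      if (el >= min_time || n_loop >= 2^20) break
      n_loop <- n_loop * as.integer(max(2, min(ceiling(min_time / max(el,
                                                                      1e-9)),
                                               1024)))
    }
    best <- el / n_loop
    for (r in seq_len(reps - 1L)) {
      best <- min(best, fun(X, scale, n_loop) / n_loop)
    }
    best
  }
  gram <- vapply(N_grid, time_method, numeric(1), fun = cpp_time_gram_evd)
  dense <- vapply(N_grid_dense, time_method, numeric(1),
                  fun = cpp_time_dense_evd)
  rbind(data.frame(method = "gram", N = N_grid, seconds = gram),
        data.frame(method = "dense", N = N_grid_dense, seconds = dense))
}

#' Fitted cost exponent from a scaling benchmark
#'
#' Estimates the growth exponent `e` of the per-call cost by fitting
#' `t(N) = a + b * N^e` with a nonnegative offset `a` (profiled weighted
#' least squares inside a one-dimensional search over `e`, residuals taken
#' on the log scale). The offset absorbs `N`-independent per-call work --
#' dominated by the fixed-size `k x k` eigensolve -- which would otherwise
#' bias a plain log-log regression towards zero at the small-`N` end of the
#' grid.
#'
#' @param bench output of [benchmark_evd_scaling()].
#' @param method `"gram"` or `"dense"`.
#' @return the fitted exponent (scalar).
#' @export
scaling_exponent <- function(bench, method = c("gram", "dense")) {
  method <- match.arg(method)
  d <- bench[bench$method == method, ]
  if (nrow(d) < 3L) stop_value("need at least 3 N values to fit an exponent")
  N <- d$N
  t <- d$seconds
  obj <- function(e) {
    X <- cbind(1, N^e)
    w <- sqrt(1 / t^2)  # relative-error weighting
    cf <- pmax(solve(crossprod(X * w), crossprod(X * w, t * w)), 0)
    pred <- pmax(X %*% cf, .Machine$double.xmin)
    sum((log(t) - log(pred))^2)
  }
  stats::optimize(obj, c(0.3, 3.5))$minimum
}
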