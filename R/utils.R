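# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @useDynLib dfconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor fft rnorm runif sd setNames quantile
#' @importFrom utils read.csv write.csv head tail
## usethis namespace: end
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_value <- function(...) {
  stop(errorCondition(paste0(...), class = c("dfconn_value_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("dfconn_config_error", "error")))
}

stop_index <- function(...) {
  stop(errorCondition(paste0(...), class = c("dfconn_index_error", "error")))
}

#' Simple timestamped logger
#' @noRd
log_msg <- function(level, stage, msg, verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  message(sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, stage, msg))
}

## 32-bit FNV-1a hash of a character string, returned as hex. Used to
## fingerprint resolved pipeline configurations in provenance sidecars.
## The multiply is split into 16-bit halves so it stays exact in doubles.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256  # xor only touches the low byte (b < 256)
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Write a file atomically (write to a temp file, then rename)
#' @noRd
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary file onto ", path)
  }
  invisible(path)
}

#' Locate local maxima of a series
#'
#' A frame is a peak when it is strictly greater than its neighbours, exceeds
#' `min(x) + height_frac * diff(range(x))`, and is at least `min_sep` frames
#' away from any larger retained peak.
#'
#' @param x numeric series.
#' @param min_sep minimum separation between retained peaks, in frames.
#' @param height_frac fraction of the series range a peak must clear above the
#'   minimum (default 0.5).
#' @return integer indices of the retained peaks, ordered by decreasing height.
#' @export
find_peaks <- function(x, min_sep = 1L, height_frac = 0.5) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  thr <- min(x) + height_frac * diff(range(x))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= thr]
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  kept
}
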