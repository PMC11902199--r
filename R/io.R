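# Readers and writers for signals and fitted objects. Everything is plain
# text (CSV + JSON sidecars) so results stay portable and diffable.

#' Read signals from disk
#'
#' Delimited text readers for the `N x T_rec` signal matrix; the
#' `orientation` flag states explicitly whether signals are rows or columns
#' (no guessing). An optional NIfTI reader (via the RNifti package, if
#' installed) flattens voxels to rows.
#'
#' @param path input file.
#' @param format `"csv"`, `"tsv"` or `"nifti"`.
#' @param orientation are signals `"rows"` (default) or `"cols"` of the
#'   delimited file?
#' @param dt sampling interval in seconds (optional).
#' @param header does the delimited file have a header row? Defaults to
#'   `TRUE`, matching the files this package writes.
#' @return a [signal_set()].
#' @export
read_signals <- function(path, format = c("csv", "tsv", "bin", "nifti"),
                         orientation = c("rows", "cols"), dt = NULL,
                         header = TRUE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_value("input file not found: ", path)
  if (format == "bin") {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    if (!file.exists(sidecar)) {
      stop_value("binary input needs its JSON sidecar (", sidecar,
                 ") for the array dimensions")
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    n <- prod(meta$dim)
    vals <- readBin(path, what = "double", n = n, endian = "little")
    if (length(vals) != n) stop_value("binary file shorter than dim says")
    return(signal_set(matrix(vals, meta$dim[1], meta$dim[2]),
                      dt = dt %||% meta$dt,
                      labels = meta$labels))
  }
  if (format == "nifti") {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop_config("reading NIfTI requires the RNifti package")
    }
    img <- RNifti::readNifti(path)
    d <- dim(img)
    mat <- matrix(as.vector(img), prod(d[-length(d)]), d[length(d)])
    return(signal_set(mat, dt = dt))
  }
  sep <- if (format == "csv") "," else "\t"
  mat <- as.matrix(read.csv(path, sep = sep, header = header))
  if (orientation == "cols") mat <- t(mat)
  signal_set(mat, dt = dt)
}

#' Write signals to disk with a JSON provenance sidecar
#'
#' `"csv"` writes delimited text (signals as rows); `"bin"` writes raw
#' little-endian doubles in column-major order. Either way a `.json`
#' sidecar records the dimensions, sampling interval, labels and the
#' preprocessing provenance.
#'
#' @param x a [signal_set()].
#' @param path output file.
#' @param format `"csv"` (default) or `"bin"`.
#' @return invisibly, the paths written.
#' @export
write_signals <- function(x, path, format = c("csv", "bin")) {
  format <- match.arg(format)
  x <- as_signal_set(x)
  if (format == "csv") {
    write_atomic(path, function(p)
      write.csv(x$data, p, row.names = FALSE))
  } else {
    write_atomic(path, function(p)
      writeBin(as.vector(x$data), p, endian = "little"))
  }
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  write_atomic(sidecar, function(p)
    jsonlite::write_json(list(dim = dim(x$data), dt = x$dt,
                              labels = x$labels,
                              provenance = x$provenance),
                         p, digits = NA, auto_unbox = TRUE, null = "null"))
  invisible(c(signals = path, sidecar = sidecar))
}

#' Serialise a fitted dfc object to a directory of text files
#'
#' Writes `eigenvalues.csv` (frames x r), `eigenvectors.csv` (the `N x r`
#' eigenvector block of each frame, stacked; `N * r + r` stored values per
#' frame rather than the `N (N - 1) / 2` of a dense upper triangle) and
#' `meta.json` (matrix type, window, scale, tolerance, sign convention).
#' Complex eigenvector series are stored as interleaved real and imaginary
#' columns.
#'
#' @param object a [dfc()] fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dfc <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- cbind(frame = object$frames, rank = object$rank, object$values)
  colnames(vals) <- c("frame", "rank",
                      paste0("lambda", seq_len(ncol(object$values))))
  p_vals <- file.path(dir, "eigenvalues.csv")
  write_atomic(p_vals, function(p) write.csv(vals, p, row.names = FALSE))
  r <- ncol(object$values)
  flat <- matrix(aperm(object$vectors, c(1L, 3L, 2L)),
                 nrow = object$N * length(object$frames), ncol = r)
  if (is.complex(flat)) {
    flat <- cbind(Re(flat), Im(flat))
    colnames(flat) <- c(paste0("re_u", seq_len(r)), paste0("im_u", seq_len(r)))
  } else {
    colnames(flat) <- paste0("u", seq_len(r))
  }
  p_vecs <- file.path(dir, "eigenvectors.csv")
  write_atomic(p_vecs, function(p) write.csv(flat, p, row.names = FALSE))
  meta <- list(type = object$type, variant = object$variant,
               N = object$N, T_rec = object$T_rec,
               window = list(T = object$window$T, taper = object$window$taper,
                             weights = object$window$weights),
               scale = object$scale, n_eigs = object$n_eigs, tol = object$tol,
               frames = range(object$frames), r = r,
               complex = is.complex(object$vectors),
               sign_convention = "largest-|entry| component rotated positive",
               values_per_frame = object$N * r + r)
  p_meta <- file.path(dir, "meta.json")
  write_atomic(p_meta, function(p)
    jsonlite::write_json(meta, p, digits = NA, auto_unbox = TRUE,
                         null = "null"))
  invisible(c(values = p_vals, vectors = p_vecs, meta = p_meta))
}

#' Read back a fit written by [write_dfc()]
#'
#' @param dir directory written by [write_dfc()].
#' @return a `dfc` object (call slot empty).
#' @export
read_dfc <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  vals <- as.matrix(read.csv(file.path(dir, "eigenvalues.csv")))
  frames <- vals[, "frame"]
  ranks <- vals[, "rank"]
  flat <- as.matrix(read.csv(file.path(dir, "eigenvectors.csv")))
  r <- meta$r
  n_frames <- nrow(vals)
  if (isTRUE(meta$complex)) {
    flat <- flat[, seq_len(r), drop = FALSE] +
      1i * flat[, r + seq_len(r), drop = FALSE]
  }
  vec <- aperm(array(as.vector(flat), c(meta$N, n_frames, r)), c(1L, 3L, 2L))
  vals <- vals[, -(1:2), drop = FALSE]
  dimnames(vals) <- NULL
  w <- window_spec(meta$window$T,
                   weights = if (meta$window$taper != "square")
                     meta$window$weights)
  structure(list(values = vals,
                 vectors = vec, rank = as.integer(ranks),
                 frames = as.integer(frames), type = meta$type,
                 variant = meta$variant, window = w, scale = meta$scale,
                 N = meta$N, T_rec = meta$T_rec, n_eigs = meta$n_eigs,
                 tol = meta$tol,
                 unit_diagonal = meta$type %in% c("correlation", "ipa",
                                                  "phase_locking",
                                                  "wavelet_coherence"),
                 fixed_trace = meta$type %in% c("correlation", "ipa",
                                                "phase_locking",
                                                "wavelet_coherence"),
                 tapered = meta$window$taper != "square", call = NULL),
            class = "dfc")
}
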