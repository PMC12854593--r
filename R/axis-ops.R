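#' Resample a spectrum onto a target axis
#'
#' Linear interpolation onto `target_axis`. Extrapolation is refused: the
#' target must lie within the source span. Metadata is preserved.
#'
#' @param x A `sors_spectrum`.
#' @param target_axis Numeric vector of target Raman shifts (cm^-1).
#' @return A `sors_spectrum` on `target_axis`.
#' @export
resample <- function(x, target_axis) {
  stopifnot(is_spectrum(x))
  target_axis <- as.numeric(target_axis)
  tol <- 1e-9 * max(1, diff(range(x$wavenumber)))
  if (min(target_axis) < min(x$wavenumber) - tol ||
      max(target_axis) > max(x$wavenumber) + tol) {
    stop(sprintf(
      "resample: target [%.6g, %.6g] outside source span [%.6g, %.6g]",
      min(target_axis), max(target_axis),
      min(x$wavenumber), max(x$wavenumber)), call. = FALSE)
  }
  it <- stats::approx(x$wavenumber, x$intensity, xout = target_axis,
                      rule = 2)$y
  spectrum(target_axis, it, x$meta)
}

#' Truncate a spectrum to an analysis window
#'
#' Retains axis points in the closed interval `[lo, hi]`. The defaults are
#' the fingerprint window used throughout the pipeline, 750-1800 cm^-1.
#'
#' @param x A `sors_spectrum`.
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return The truncated `sors_spectrum`.
#' @export
truncate_spectrum <- function(x, lo = 750, hi = 1800) {
  stopifnot(is_spectrum(x))
  if (lo >= hi) stop("truncate_spectrum: need lo < hi", call. = FALSE)
  keep <- x$wavenumber >= lo & x$wavenumber <= hi
  if (sum(keep) < 2L) {
    stop(sprintf(
      "truncate_spectrum: window [%g, %g] overlaps < 2 axis points", lo, hi),
      call. = FALSE)
  }
  spectrum(x$wavenumber[keep], x$intensity[keep], x$meta)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of spectra on a common axis; an axis mismatch is
#' a hard error (resample first). Metadata records the contributing
#' replicate ids.
#'
#' @param spectra List of `sors_spectrum` objects (at least one).
#' @return A `sors_spectrum` with the mean intensity.
#' @export
average_replicates <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 1L) {
    stop("average_replicates: need at least one spectrum", call. = FALSE)
  }
  stopifnot(all(vapply(spectra, is_spectrum, logical(1))))
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (!same_axis(ref, s)) stop_axis_mismatch("average_replicates")
  }
  m <- rowMeans(vapply(spectra, function(s) s$intensity,
                       numeric(length(ref$wavenumber))))
  meta <- ref$meta
  reps <- unlist(lapply(spectra, function(s) s$meta$replicate_id %||% NA_character_))
  meta$averaged_replicates <- paste(reps, collapse = ";")
  meta$n_averaged <- length(spectra)
  spectrum(ref$wavenumber, m, meta)
}

# Stack a list of spectra (common axis) into a samples x wavenumbers matrix.
spectra_matrix <- function(spectra) {
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (!same_axis(ref, s)) stop_axis_mismatch("spectra_matrix")
  }
  t(vapply(spectra, function(s) s$intensity, numeric(length(ref$wavenumber))))
}
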