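#' Construct a Raman spectrum
#'
#' The basic currency of the package: a strictly increasing Raman-shift axis
#' (cm^-1), one intensity per axis point, and free-form metadata (sample id,
#' replicate id, channel, ...).
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1. Must be finite
#'   and strictly increasing (a descending axis is reordered, together with
#'   the intensities).
#' @param intensity Numeric vector of intensities, one per axis point.
#'   Raw-channel spectra (`channel` of `"zero"` or `"offset"`) must be
#'   non-negative; processed spectra may contain negative values.
#' @param meta Named list of metadata. The key `channel` is conventionally one
#'   of `"zero"`, `"offset"` or `"processed"`.
#' @return An object of class `sors_spectrum`.
#' @export
spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) < 2L) {
    stop("spectrum: axis must have at least 2 points", call. = FALSE)
  }
  if (length(intensity) != length(wavenumber)) {
    stop(sprintf("spectrum: axis has %d points but intensity has %d",
                 length(wavenumber), length(intensity)), call. = FALSE)
  }
  if (!all(is.finite(wavenumber))) {
    stop("spectrum: axis contains non-finite values", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("spectrum: intensity contains non-finite values", call. = FALSE)
  }
  d <- diff(wavenumber)
  if (all(d < 0)) {          # descending input: reorder consistently
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
  } else if (any(d <= 0)) {
    stop("spectrum: axis must be strictly monotone", call. = FALSE)
  }
  ch <- meta$channel
  if (!is.null(ch) && ch %in% c("zero", "offset") && any(intensity < 0)) {
    stop(sprintf("spectrum: raw '%s' channel has negative intensities", ch),
         call. = FALSE)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity, meta = meta),
            class = "sors_spectrum")
}

#' @export
print.sors_spectrum <- function(x, ...) {
  cat(sprintf("<sors_spectrum: %d points, %.1f-%.1f cm-1", length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  if (!is.null(x$meta$channel)) cat(", channel=", x$meta$channel, sep = "")
  if (!is.null(x$meta$sample_id)) cat(", sample=", x$meta$sample_id, sep = "")
  cat(">\n")
  invisible(x)
}

#' @export
length.sors_spectrum <- function(x) length(x$wavenumber)

is_spectrum <- function(x) inherits(x, "sors_spectrum")

same_axis <- function(a, b, tol = 1e-9) {
  length(a$wavenumber) == length(b$wavenumber) &&
    max(abs(a$wavenumber - b$wavenumber)) <= tol
}

stop_axis_mismatch <- function(what) {
  stop(sprintf("%s: spectra are not on a common axis; resample() first", what),
       call. = FALSE)
}

#' Construct a paired zero/offset SORS measurement
#'
#' One replicate of one sample: the spectrum acquired at zero source-collector
#' separation (surface / container dominated) and the spectrum at a lateral
#' offset (subsurface / fluid enriched). Both must be on an identical axis;
#' resample first if they are not.
#'
#' @param sample_id,replicate_id Identifiers.
#' @param zero,offset `sors_spectrum` objects on an identical axis.
#' @param offset_distance Lateral offset in mm (must be > 0); default 5.5 mm.
#' @param ground_truth Optional named list recording simulator truth.
#' @return An object of class `sors_measurement`.
#' @export
sors_measurement <- function(sample_id, replicate_id, zero, offset,
                             offset_distance = 5.5, ground_truth = NULL) {
  stopifnot(is_spectrum(zero), is_spectrum(offset))
  if (!same_axis(zero, offset)) stop_axis_mismatch("sors_measurement")
  if (!is.numeric(offset_distance) || offset_distance <= 0) {
    stop("sors_measurement: offset_distance must be > 0", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 replicate_id = as.character(replicate_id),
                 zero = zero, offset = offset,
                 offset_distance = offset_distance,
                 ground_truth = ground_truth),
            class = "sors_measurement")
}

#' @export
print.sors_measurement <- function(x, ...) {
  cat(sprintf("<sors_measurement %s/%s: %d points, offset %.1f mm>\n",
              x$sample_id, x$replicate_id, length(x$zero), x$offset_distance))
  invisible(x)
}

#' Construct a sample record
#'
#' Groups the 2-3 replicate SORS measurements typically taken per specimen,
#' with an optional expected label from documentation.
#'
#' @param sample_id Identifier shared by all measurements.
#' @param measurements List of `sors_measurement` objects (at least one).
#' @param expected_label Free-text expected fluid (may be `NA`).
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, measurements, expected_label = NA_character_) {
  if (length(measurements) < 1L) {
    stop("sample_record: at least one measurement required", call. = FALSE)
  }
  ok <- vapply(measurements, function(m) inherits(m, "sors_measurement") &&
                 m$sample_id == sample_id, logical(1))
  if (!all(ok)) {
    stop("sample_record: all measurements must share sample_id ", sample_id,
         call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 expected_label = expected_label,
                 measurements = measurements),
            class = "sample_record")
}
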