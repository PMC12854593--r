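#' Read a spectrum from disk
#'
#' Two dialects are supported. `csv2col` is the package's plain-text exchange
#' format: optional `# key: value` header lines followed by
#' `wavenumber,intensity` rows (comma delimiter, decimal point). `jcampdx`
#' reads a minimal JCAMP-DX file with an uncompressed (AFFN)
#' `##XYDATA=(X++(Y..Y))` block.
#'
#' @param path Path to the file.
#' @param dialect `"csv2col"` (default) or `"jcampdx"`.
#' @return A `sors_spectrum`; header keys become metadata. A descending axis
#'   in the file is returned ascending with intensities reordered.
#' @export
read_spectrum <- function(path, dialect = c("csv2col", "jcampdx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("read_spectrum: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "csv2col") read_csv2col(lines, path) else read_jcampdx(lines, path)
}

read_csv2col <- function(lines, path) {
  is_header <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[is_header]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- utils::type.convert(m[3], as.is = TRUE)
  }
  body <- lines[!is_header & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    stop("read_spectrum: no data rows in ", path, call. = FALSE)
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- which(nfield != 2L)[1L]
    stop(sprintf(
      "read_spectrum: csv2col requires exactly 2 columns; row %d of %s has %d",
      bad, path, nfield[bad]), call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(wn) || anyNA(it)) {
    bad <- which(is.na(wn) | is.na(it))[1L]
    stop(sprintf("read_spectrum: non-numeric value at data row %d of %s",
                 bad, path), call. = FALSE)
  }
  spectrum(wn, it, meta)
}

read_jcampdx <- function(lines, path) {
  meta <- list()
  for (h in grep("^##", lines, value = TRUE)) {
    m <- regmatches(h, regexec("^##([^=]+)=\\s*(.*?)\\s*$", h))[[1]]
    if (length(m) == 3L && !grepl("^XYDATA", m[2])) meta[[tolower(m[2])]] <- m[3]
  }
  start <- grep("^##XYDATA\\s*=\\s*\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (length(start) != 1L) {
    stop("read_spectrum: no single ##XYDATA=(X++(Y..Y)) block in ", path,
         call. = FALSE)
  }
  end <- grep("^##", lines)
  end <- end[end > start]
  end <- if (length(end)) min(end) - 1L else length(lines)
  xf <- as.numeric(meta[["xfactor"]] %||% 1)
  yf <- as.numeric(meta[["yfactor"]] %||% 1)
  wn <- numeric(0); it <- numeric(0)
  for (i in seq(start + 1L, end)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t,]+")[[1]]))
    if (length(vals) < 2L || anyNA(vals)) {
      stop(sprintf("read_spectrum: malformed XYDATA line %d of %s", i, path),
           call. = FALSE)
    }
    ys <- vals[-1L]
    x0 <- vals[1L] * xf
    # X of subsequent Y values interpolated from the per-line start values
    wn <- c(wn, x0, rep(NA_real_, length(ys) - 1L))
    it <- c(it, ys * yf)
  }
  # fill implicit X positions assuming a uniform grid across the block
  known <- which(!is.na(wn))
  if (length(known) >= 2L) {
    step <- (wn[known[2L]] - wn[known[1L]]) / (known[2L] - known[1L])
  } else {
    npt <- as.numeric(meta[["npoints"]] %||% length(it))
    lastx <- as.numeric(meta[["lastx"]] %||% NA)
    step <- if (is.finite(lastx)) (lastx - wn[1L]) / (npt - 1) else 1
  }
  wn <- wn[1L] + step * (seq_along(it) - 1L)
  spectrum(wn, it, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum as a csv2col text file
#'
#' Metadata entries of length one are written as `# key: value` header lines;
#' numbers are serialized with full double precision so a read/write
#' round-trip preserves the spectrum to better than 1e-9.
#'
#' @param x A `sors_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(is_spectrum(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(x$meta)) {
    v <- x$meta[[k]]
    if (length(v) == 1L && (is.character(v) || is.numeric(v) || is.logical(v))) {
      writeLines(sprintf("# %s: %s", k, format(v, digits = 17)), con)
    }
  }
  writeLines(paste(sprintf("%.12g", x$wavenumber),
                   sprintf("%.12g", x$intensity), sep = ","), con)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `sample_id`, `replicate_id`, `zero_path`,
#' `offset_path`, `expected_label`, `offset_mm`. Paths are resolved relative
#' to the manifest's directory. Replicates whose files are missing are skipped
#' with a warning; the remaining samples are unaffected.
#'
#' @param path Manifest CSV path.
#' @return A list of `sample_record` objects.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest: file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate_id", "zero_path", "offset_path",
            "expected_label", "offset_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("read_manifest: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  root <- dirname(normalizePath(path))
  records <- list()
  for (sid in unique(tab$sample_id)) {
    rows <- tab[tab$sample_id == sid, , drop = FALSE]
    ms <- list()
    for (i in seq_len(nrow(rows))) {
      zp <- file.path(root, rows$zero_path[i])
      op <- file.path(root, rows$offset_path[i])
      if (!file.exists(zp) || !file.exists(op)) {
        warning(sprintf("read_manifest: skipping %s/%s (missing file)",
                        sid, rows$replicate_id[i]), call. = FALSE)
        next
      }
      zero <- read_spectrum(zp)
      offset <- read_spectrum(op)
      zero$meta$channel <- "zero"; offset$meta$channel <- "offset"
      ms[[length(ms) + 1L]] <- sors_measurement(
        sid, rows$replicate_id[i], zero, offset,
        offset_distance = rows$offset_mm[i])
    }
    if (length(ms) == 0L) {
      warning("read_manifest: sample ", sid, " has no readable replicates; dropped",
              call. = FALSE)
      next
    }
    records[[sid]] <- sample_record(sid, ms, rows$expected_label[1L])
  }
  records
}
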