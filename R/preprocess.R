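#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the SORS differential-processing chain.
#'
#' @param sf_window Optional `c(lo, hi)` wavenumber interval (cm^-1) used for
#'   windowed scaling-factor estimation. For the forward direction the window
#'   should be container-dominant; for the reverse direction fluid-dominant.
#'   When `NULL` (default) the scaling factor is found by a deterministic grid
#'   search on the negativity penalty instead.
#' @param sf_grid `c(min, max, step)` for the grid search; default
#'   `c(0, 3, 0.001)`.
#' @param sf_grid_rel_tol Relative tolerance (fraction of the penalty range
#'   over the grid) within which the largest scaling factor is accepted;
#'   default `1e-6`. See [estimate_scaling_factor()].
#' @param baseline_order Polynomial order for baseline removal (default 5).
#' @param baseline_iterations Clipping iterations for the baseline fit
#'   (default 20).
#' @param snv_epsilon Lower guard on the standard deviation in SNV scaling
#'   (default 1e-12).
#' @param truncate_lo,truncate_hi Analysis window in cm^-1 (defaults 750 and
#'   1800).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(sf_window = NULL, sf_grid = c(0, 3, 0.001),
                              sf_grid_rel_tol = 1e-6,
                              baseline_order = 5L, baseline_iterations = 20L,
                              snv_epsilon = 1e-12,
                              truncate_lo = 750, truncate_hi = 1800) {
  stopifnot(baseline_order >= 0, snv_epsilon > 0,
            length(sf_grid) == 3, sf_grid[1] >= 0, sf_grid[2] > sf_grid[1],
            sf_grid[3] > 0, truncate_lo < truncate_hi)
  if (!is.null(sf_window)) stopifnot(length(sf_window) == 2, sf_window[1] < sf_window[2])
  structure(list(sf_window = sf_window, sf_grid = sf_grid,
                 sf_grid_rel_tol = sf_grid_rel_tol,
                 baseline_order = as.integer(baseline_order),
                 baseline_iterations = as.integer(baseline_iterations),
                 snv_epsilon = snv_epsilon,
                 truncate_lo = truncate_lo, truncate_hi = truncate_hi),
            class = "preprocess_config")
}

#' Estimate the zero/offset scaling factor
#'
#' The scaling factor (SF) rescales one channel before subtraction so that the
#' unwanted layer cancels. Forward processing removes the container from the
#' offset channel (`offset - SF * zero`); reverse processing removes the fluid
#' from the zero channel (`zero - SF * offset`).
#'
#' Two deterministic estimators are provided. When `config$sf_window` is set,
#' SF is the non-negative least-squares coefficient of the subtracted channel
#' against the retained channel restricted to that window (for a single
#' coefficient this is the clamped ordinary LS ratio). Otherwise SF is found
#' on the grid `config$sf_grid` from the negativity penalty
#' `P(SF) = sum(pmax(0, -(retained - SF * subtracted))^2)`: for non-negative
#' spectra `P` is non-decreasing in SF and stays at its minimum until SF
#' exceeds the point where the unwanted layer is exactly cancelled, so the
#' estimator returns the LARGEST grid SF whose penalty is within
#' `config$sf_grid_rel_tol` of the grid minimum (relative to the penalty range
#' over the grid). The grid is scanned coarsely first and refined around the
#' knee.
#'
#' The knee can only locate the nulling ratio of a layer that dominates the
#' channels somewhere on the axis. The container does dominate the raw
#' channels (its fluorescence or Raman floor is present everywhere), so the
#' forward estimate runs on the raw channels. The fluid's bands only
#' dominate once the smooth container envelope is removed, so the reverse
#' estimate runs the same knee on peak-clipped baseline-corrected copies of
#' both channels, and is capped at `0.5 / SF_forward`: the subsurface
#' enrichment invariant bounds the true fluid-nulling ratio by
#' `1 / SF_forward`, and the cap guarantees the container branch is never
#' self-cancelled when the zero channel's fluid content is too weak to
#' locate (watery fluids behind strongly fluorescing glass). Both estimates
#' are deterministic; the reverse one is intrinsically the less precise of
#' the two (the quantity it targets is buried under the container signal),
#' which downstream stages tolerate because the container branch is used for
#' material typing, not quantification.
#'
#' @param zero,offset `sors_spectrum` objects on a common axis.
#' @param config A [preprocess_config()].
#' @param direction `"forward"` (isolate fluid) or `"reverse"` (isolate
#'   container).
#' @return A single non-negative scaling factor.
#' @export
estimate_scaling_factor <- function(zero, offset, config = preprocess_config(),
                                    direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(is_spectrum(zero), is_spectrum(offset))
  if (!same_axis(zero, offset)) stop_axis_mismatch("estimate_scaling_factor")
  if (direction == "forward") {
    retained <- offset$intensity; subtracted <- zero$intensity
  } else {
    retained <- zero$intensity; subtracted <- offset$intensity
  }
  if (all(abs(subtracted) < .Machine$double.eps)) {
    stop("estimate_scaling_factor: subtracted channel is identically zero",
         call. = FALSE)
  }
  if (!is.null(config$sf_window)) {
    w <- zero$wavenumber >= config$sf_window[1] & zero$wavenumber <= config$sf_window[2]
    if (sum(w) < 2L) {
      stop("estimate_scaling_factor: sf_window overlaps < 2 axis points",
           call. = FALSE)
    }
    denom <- sum(subtracted[w]^2)
    # no shared component in the window (numerical zero relative to the
    # channel's own scale) => nothing to cancel
    if (denom <= 1e-20 * max(subtracted)^2 * sum(w)) return(0)
    return(max(0, sum(retained[w] * subtracted[w]) / denom))
  }
  if (direction == "forward") {
    return(sf_knee(retained, subtracted, config$sf_grid, config$sf_grid_rel_tol))
  }
  # reverse: the fluid only dominates in the detail domain, so run the knee
  # on peak-clipped baseline-corrected copies of both channels; the cap
  # guards against self-cancelling the container when the zero channel's
  # fluid content is too weak to locate (see Details)
  sf_f <- sf_knee(offset$intensity, zero$intensity, config$sf_grid,
                  config$sf_grid_rel_tol)
  bc <- function(i) {
    s <- spectrum(zero$wavenumber, i, list(channel = "processed"))
    baseline_correct(s, config$baseline_order,
                     config$baseline_iterations)$intensity
  }
  sf_r <- sf_knee(bc(retained), bc(subtracted), config$sf_grid,
                  config$sf_grid_rel_tol)
  min(sf_r, 0.5 / max(sf_f, 1e-9))
}

# Largest SF on the grid whose negativity penalty is within rel_tol of the
# minimum (relative to the penalty range), located coarse-then-fine. Both
# channels are clamped at zero so the penalty is non-decreasing in SF.
sf_knee <- function(retained, subtracted, grid, rel_tol) {
  retained <- pmax(retained, 0)
  subtracted <- pmax(subtracted, 0)
  penalty <- function(sf_values) {
    vapply(sf_values, function(sf) {
      r <- retained - sf * subtracted
      sum(pmin(r, 0)^2)
    }, numeric(1))
  }
  pick <- function(sfs, thr = NULL) {
    p <- penalty(sfs)
    if (is.null(thr)) {
      rng <- max(p) - min(p)
      thr <- min(p) + if (rng > 0) rel_tol * rng else 0
    }
    ok <- which(p <= thr)
    list(sf = sfs[max(ok)], thr = thr)
  }
  coarse_step <- max(grid[3], (grid[2] - grid[1]) / 200)
  coarse <- pick(seq(grid[1], grid[2], by = coarse_step))
  lo <- max(grid[1], coarse$sf - coarse_step)
  hi <- min(grid[2], coarse$sf + coarse_step)
  pick(seq(lo, hi, by = grid[3]), thr = coarse$thr)$sf
}

#' Scaled SORS subtraction (fluid isolation)
#'
#' Returns `offset - sf * zero`, cancelling the container/surface layer and
#' isolating the fluid signature. The result is marked as a processed fluid
#' channel.
#'
#' @param zero,offset `sors_spectrum` objects on a common axis.
#' @param sf Non-negative scaling factor.
#' @return A processed `sors_spectrum`.
#' @export
sors_subtract <- function(zero, offset, sf) {
  stopifnot(is_spectrum(zero), is_spectrum(offset), sf >= 0)
  if (!same_axis(zero, offset)) stop_axis_mismatch("sors_subtract")
  meta <- offset$meta
  meta$channel <- "processed"; meta$layer <- "fluid"; meta$sf <- sf
  spectrum(offset$wavenumber, offset$intensity - sf * zero$intensity, meta)
}

#' Reverse SORS subtraction (container isolation)
#'
#' Returns `zero - sf * offset`, cancelling the fluid and isolating the
#' container/surface signature.
#'
#' @inheritParams sors_subtract
#' @return A processed `sors_spectrum`.
#' @export
reverse_sors <- function(zero, offset, sf) {
  stopifnot(is_spectrum(zero), is_spectrum(offset), sf >= 0)
  if (!same_axis(zero, offset)) stop_axis_mismatch("reverse_sors")
  meta <- zero$meta
  meta$channel <- "processed"; meta$layer <- "container"; meta$sf <- sf
  spectrum(zero$wavenumber, zero$intensity - sf * offset$intensity, meta)
}

#' Iterative polynomial baseline removal
#'
#' Fits a polynomial of the given order to the spectrum; at each iteration
#' points lying above the current fit are replaced by the fit value, which
#' progressively excludes peaks from the fit, and the polynomial is refitted.
#' The final polynomial is subtracted.
#'
#' @param x A `sors_spectrum`.
#' @param order Polynomial order (default 5).
#' @param iterations Clipping iterations (default 20).
#' @return The baseline-corrected `sors_spectrum`.
#' @export
baseline_correct <- function(x, order = 5L, iterations = 20L) {
  stopifnot(is_spectrum(x), order >= 0, iterations >= 1)
  n <- length(x$wavenumber)
  if (n <= order + 1L) {
    stop(sprintf("baseline_correct: %d points cannot support order %d", n, order),
         call. = FALSE)
  }
  # orthonormal polynomial basis on the (centred, scaled) axis for stability
  basis <- cbind(1 / sqrt(n), stats::poly(x$wavenumber, degree = order))
  y <- x$intensity
  fit <- y
  for (i in seq_len(iterations)) {
    coef <- crossprod(basis, y)          # basis has orthonormal columns
    fit <- drop(basis %*% coef)
    y <- pmin(y, fit)
  }
  meta <- x$meta
  meta$baseline <- sprintf("poly%d x%d", order, iterations)
  meta$channel <- "processed"
  spectrum(x$wavenumber, x$intensity - fit, meta)
}

#' Standard normal variate normalization
#'
#' Centres each spectrum to mean zero and scales to unit standard deviation
#' over its own points: `(I - mean(I)) / max(sd(I), epsilon)`. Constant
#' spectra map to all zeros via the epsilon guard.
#'
#' @param x A `sors_spectrum` with at least 2 points.
#' @param epsilon Lower guard on the standard deviation (default 1e-12).
#' @return The normalized `sors_spectrum`.
#' @export
snv <- function(x, epsilon = 1e-12) {
  stopifnot(is_spectrum(x), epsilon > 0)
  i <- x$intensity
  out <- (i - mean(i)) / max(stats::sd(i), epsilon)
  meta <- x$meta
  meta$snv <- TRUE
  spectrum(x$wavenumber, out, meta)
}

#' Run the full differential-processing chain on one measurement
#'
#' Truncates both channels to the analysis window, estimates forward and
#' reverse scaling factors, and forms both subtractions. The fluid branch is
#' additionally baseline-corrected and SNV-normalized; the container branch is
#' left un-normalized so that curve-resolution scores retain physical
#' magnitude. A measurement with no zero/offset contrast (fluid branch with
#' essentially no energy) is flagged `degenerate`.
#'
#' Scaling-factor error leaves a small multiple of the container spectrum in
#' the fluid branch. For glasses that leakage is smooth and the polynomial
#' baseline absorbs it, but sharp Raman bands of polymer/acrylic containers
#' survive the baseline and would distort classification. The fluid branch
#' is therefore also produced in deflated representations, one per container
#' reference: the polynomial-detail component of the rendered reference
#' profile (the sharp Raman bands of PMMA/LDPE/PP, or the part of a glass
#' fluorescence envelope that a polynomial cannot absorb) is regressed out
#' of the fluid branch's detail. Each deflation is a fixed linear operator,
#' so calibration and queries can be compared consistently within any one
#' representation. The measurement's container family is read off its
#' reverse-SORS sharpness (detail energy above 5% of total energy marks a
#' polymer; glasses sit far below) and the specific material by cosine match
#' of the container detail against the references of that family; only that
#' one interfering container direction is then removed from the feature
#' space.
#'
#' @param m A `sors_measurement`.
#' @param config A [preprocess_config()].
#' @return A list of class `processed_pair` with elements `fluid_spectrum`
#'   (plain representation), `fluid_deflated` (named list of
#'   single-reference-orthogonalized variants, one per container material),
#'   `container_spectrum`, `sf_forward`, `sf_reverse`, `degenerate`,
#'   `container_sharpness`, `container_match` (best-cosine reference of the
#'   container detail within its family), `sample_id`, `replicate_id`.
#' @export
process_measurement <- function(m, config = preprocess_config()) {
  stopifnot(inherits(m, "sors_measurement"))
  res <- tryCatch({
    zero <- truncate_spectrum(m$zero, config$truncate_lo, config$truncate_hi)
    offset <- truncate_spectrum(m$offset, config$truncate_lo, config$truncate_hi)
    sf_f <- estimate_scaling_factor(zero, offset, config, "forward")
    sf_r <- estimate_scaling_factor(zero, offset, config, "reverse")
    fluid_raw <- sors_subtract(zero, offset, sf_f)
    container <- reverse_sors(zero, offset, sf_r)
    n <- length(zero$wavenumber)
    basis <- cbind(1 / sqrt(n),
                   stats::poly(zero$wavenumber, degree = config$baseline_order))
    detail <- function(y) y - drop(basis %*% crossprod(basis, y))
    cd <- detail(container$intensity)
    sharp <- sum(cd^2) / max(sum(container$intensity^2), .Machine$double.eps)
    refs <- container_library()
    R <- vapply(refs, function(ref) {
      render_component(ref, zero$wavenumber)$intensity
    }, numeric(n))
    Rd <- apply(R, 2L, detail)
    fd <- detail(fluid_raw$intensity)
    match_cos <- apply(Rd, 2L, cosine_similarity, b = cd)
    polymer <- vapply(refs, function(ref) ref$kind == "polymer", logical(1))
    if (!(sharp > 0.05)) match_cos[polymer] <- -Inf else {
      match_cos[!polymer] <- -Inf
    }
    # a genuine fluid branch carries at least a few percent of the offset
    # channel's amplitude; anything below 2% is no zero/offset contrast
    degenerate <- max(abs(fluid_raw$intensity)) <
      0.02 * max(abs(offset$intensity), .Machine$double.eps)
    finish <- function(s) {
      if (degenerate) s else {
        snv(baseline_correct(s, config$baseline_order,
                             config$baseline_iterations),
            config$snv_epsilon)
      }
    }
    deflated <- lapply(seq_along(refs), function(j) {
      beta <- sum(fd * Rd[, j]) / max(sum(Rd[, j]^2), .Machine$double.eps)
      s <- fluid_raw
      s$intensity <- fluid_raw$intensity - beta * R[, j]
      finish(s)
    })
    names(deflated) <- names(refs)
    list(fluid_spectrum = finish(fluid_raw),
         fluid_deflated = deflated,
         container_spectrum = container,
         sf_forward = sf_f, sf_reverse = sf_r, degenerate = degenerate,
         container_sharpness = sharp,
         container_match = names(refs)[which.max(match_cos)],
         sample_id = m$sample_id, replicate_id = m$replicate_id)
  }, error = function(e) {
    stop(sprintf("process_measurement [%s/%s]: %s", m$sample_id,
                 m$replicate_id, conditionMessage(e)), call. = FALSE)
  })
  structure(res, class = "processed_pair")
}
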