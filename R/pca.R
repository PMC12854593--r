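#' Principal component analysis of a spectra matrix
#'
#' Mean-centres the rows-as-samples matrix and decomposes it by singular value
#' decomposition. Loadings are sign-fixed so that each loading's
#' largest-magnitude element is positive, making the decomposition fully
#' deterministic.
#'
#' @param x Numeric matrix, samples in rows, wavenumbers in columns (>= 2
#'   rows).
#' @param n_components Number of PCs to retain;
#'   `n_components <= min(nrow - 1, ncol)`.
#' @return A list of class `pca_model` with `mean` (column means), `loadings`
#'   (ncol x n_components, orthonormal columns), `explained_variance`
#'   (fractions of total variance, non-increasing), `sdev`, and
#'   `n_components`.
#' @export
fit_pca <- function(x, n_components = min(nrow(x) - 1L, ncol(x))) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("fit_pca: need >= 2 rows", call. = FALSE)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax) {
    stop(sprintf("fit_pca: n_components %d exceeds min(rows-1, cols) = %d",
                 n_components, kmax), call. = FALSE)
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0, nv = kmax)
  load <- sv$v
  # deterministic sign convention
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  var_all <- sv$d[seq_len(kmax)]^2 / (nrow(x) - 1L)
  total <- sum(xc^2) / (nrow(x) - 1L)
  structure(list(mean = mu,
                 loadings = load[, seq_len(n_components), drop = FALSE],
                 explained_variance = var_all[seq_len(n_components)] / total,
                 sdev = sqrt(var_all[seq_len(n_components)]),
                 n_components = as.integer(n_components)),
            class = "pca_model")
}

#' Project spectra into an existing PCA space
#'
#' @param pca A [fit_pca()] model.
#' @param x Numeric matrix (or single numeric vector) on the model's axis.
#' @return Score matrix, one row per input row, `n_components` columns.
#' @export
pca_project <- function(pca, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(pca$mean)) {
    stop(sprintf("pca_project: %d columns, model expects %d",
                 ncol(x), length(pca$mean)), call. = FALSE)
  }
  sweep(x, 2L, pca$mean) %*% pca$loadings
}

#' Reconstruct spectra from scores
#'
#' @param pca A [fit_pca()] model.
#' @param scores Score matrix.
#' @return Reconstructed data matrix (approximate unless all PCs retained).
#' @export
pca_reconstruct <- function(pca, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  sweep(scores %*% t(pca$loadings), 2L, pca$mean, `+`)
}

#' Confidence ellipse of a 2-D score cloud
#'
#' Centre = mean; shape = empirical covariance scaled by the chi-square
#' quantile with 2 degrees of freedom at the requested level (the usual 95%
#' score-plot ellipse). A degenerate (rank-deficient) covariance yields a
#' zero-area ellipse along the missing direction.
#'
#' @param scores_2d Numeric matrix with 2 columns and >= 3 rows.
#' @param level Coverage level (default 0.95).
#' @param label Optional class label stored in the result.
#' @return A list of class `score_ellipse` with `center`, `covariance`,
#'   `level`, `radii` (semi-axis lengths), `angle` (radians), `label`.
#' @export
confidence_ellipse <- function(scores_2d, level = 0.95, label = NA_character_) {
  scores_2d <- as.matrix(scores_2d)
  if (ncol(scores_2d) != 2L) {
    stop("confidence_ellipse: scores must have 2 columns", call. = FALSE)
  }
  if (nrow(scores_2d) < 3L) {
    stop("confidence_ellipse: need >= 3 points", call. = FALSE)
  }
  ctr <- colMeans(scores_2d)
  cv <- stats::cov(scores_2d)
  cv <- (cv + t(cv)) / 2
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)             # PSD guard for degenerate clouds
  q <- stats::qchisq(level, df = 2)
  structure(list(center = ctr, covariance = cv, level = level,
                 radii = sqrt(q * vals),
                 angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
                 label = label),
            class = "score_ellipse")
}

#' Points of an ellipse outline (for plotting)
#'
#' @param ellipse A [confidence_ellipse()] result.
#' @param n Number of outline points.
#' @return A two-column matrix of xy coordinates.
#' @export
ellipse_outline <- function(ellipse, n = 100L) {
  th <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(ellipse$radii[1] * cos(th), ellipse$radii[2] * sin(th))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(circ %*% t(rot), 2L, ellipse$center, `+`)
}

#' Is a point inside a confidence ellipse?
#'
#' Mahalanobis test against the chi-square quantile defining the ellipse.
#'
#' @param ellipse A [confidence_ellipse()] result.
#' @param pts Two-column matrix of points (or a length-2 vector).
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  q <- stats::qchisq(ellipse$level, df = 2)
  d <- tryCatch(stats::mahalanobis(pts, ellipse$center, ellipse$covariance),
                error = function(e) rep(Inf, nrow(pts)))
  d <= q
}
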