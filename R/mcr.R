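#' Non-negative least squares for many right-hand sides
#'
#' Solves `min ||A X - B||_F` subject to `X >= 0`, column by column, using the
#' fast combinatorial active-set strategy: columns sharing a passive set are
#' solved together through the normal equations, and active-set updates follow
#' the standard Lawson-Hanson inner loop. Intended for the small
#' coefficient dimensions of curve resolution (a few components, many
#' wavenumbers/samples).
#'
#' @param A Numeric matrix (m x k), full column rank assumed.
#' @param B Numeric matrix (m x n) of right-hand sides.
#' @param max_iter Safety cap on active-set sweeps.
#' @return A k x n non-negative coefficient matrix.
#' @export
nnls_multi <- function(A, B, max_iter = 30L * ncol(A)) {
  A <- as.matrix(A); B <- as.matrix(B)
  k <- ncol(A); n <- ncol(B)
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  solve_passive <- function(P, rhs) {
    # rhs: k x (cols) slice of AtB; P: logical k-vector passive set
    out <- matrix(0, k, ncol(rhs))
    if (any(P)) {
      out[P, ] <- solve(AtA[P, P, drop = FALSE], rhs[P, , drop = FALSE])
    }
    out
  }
  # start from the unconstrained solution; clamp-derived passive sets
  X <- solve(AtA, AtB)
  P <- X > 0
  X[!P] <- 0
  for (iter in seq_len(max_iter)) {
    # re-solve all columns grouped by passive set
    key <- apply(P, 2L, function(p) paste(as.integer(p), collapse = ""))
    for (kk in unique(key)) {
      cols <- which(key == kk)
      X[, cols] <- solve_passive(P[, cols[1L]], AtB[, cols, drop = FALSE])
    }
    # feasibility: passive coefficients must be >= 0
    infeas <- P & (X < -1e-12)
    if (any(infeas)) {
      # drop the most negative passive variable per infeasible column
      for (j in which(colSums(infeas) > 0)) {
        drop_i <- which.min(replace(X[, j], !P[, j], Inf))
        P[drop_i, j] <- FALSE
        X[drop_i, j] <- 0
      }
      next
    }
    X[X < 0] <- 0
    # optimality: gradient w = AtB - AtA X must be <= 0 on the active set
    W <- AtB - AtA %*% X
    add <- (!P) & (W > 1e-10 * max(1, max(abs(AtB))))
    if (!any(add)) break
    for (j in which(colSums(add) > 0)) {
      add_i <- which.max(replace(W[, j], P[, j], -Inf))
      P[add_i, j] <- TRUE
    }
  }
  X[X < 0] <- 0
  dimnames(X) <- list(colnames(A), colnames(B))
  X
}

# Deterministic non-negative double-SVD initialization (NNDSVD): each singular
# pair contributes whichever of its positive/negative parts carries more
# energy. Zeros are left for ALS to fill.
nndsvd_init <- function(x, k) {
  sv <- svd(x, nu = k, nv = k)
  W <- matrix(0, nrow(x), k); H <- matrix(0, k, ncol(x))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_p <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      n_n <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (n_p >= n_n && n_p > 0) {
        W[, j] <- sqrt(sv$d[j] * n_p) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * n_p) * vp / sqrt(sum(vp^2))
      } else if (n_n > 0) {
        W[, j] <- sqrt(sv$d[j] * n_n) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * n_n) * vn / sqrt(sum(vn^2))
      }
    }
  }
  list(C = W, S = H)
}

#' Multivariate curve resolution by alternating non-negative least squares
#'
#' Factorizes a non-negative spectra matrix `X` (samples x wavenumbers) as
#' `X ~ C S` with `C >= 0` (scores, samples x components) and `S >= 0`
#' (component spectra, components x wavenumbers). Rows with negative entries
#' are min-shifted to zero first (shifts recorded). Initialization is a
#' deterministic SVD-based non-negative start, optionally perturbed by a tiny
#' seeded jitter; each half-step is an exact non-negative least-squares solve,
#' so the reconstruction error is non-increasing. Iteration stops when the
#' relative Frobenius change of the reconstruction drops below `tol` or at
#' `max_iter` (then `converged` is `FALSE`; no error is raised). Components
#' are ordered by decreasing total score mass and scaled so each component
#' spectrum has unit maximum.
#'
#' @param x Numeric matrix, samples in rows.
#' @param n_components Number of components (default 6).
#' @param tol Relative reconstruction-change tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 2000).
#' @param seed Seed for the (tiny) initialization jitter; `NULL` for none.
#' @return A list of class `mcr_model` with `C` (scores), `S` (component
#'   spectra), `n_components`, `converged`, `iterations`, `final_change`,
#'   `reconstruction_error` (relative Frobenius), `row_shifts`.
#' @export
fit_mcr <- function(x, n_components = 6L, tol = 1e-8, max_iter = 2000L,
                    seed = NULL) {
  x <- as.matrix(x)
  if (n_components > min(dim(x))) {
    stop(sprintf("fit_mcr: n_components %d exceeds min(dim) = %d",
                 n_components, min(dim(x))), call. = FALSE)
  }
  shifts <- pmin(apply(x, 1L, min), 0)
  xs <- x - shifts                       # min-shift, never clip
  init <- nndsvd_init(xs, n_components)
  C <- init$C; S <- init$S
  if (!is.null(seed)) {
    jit <- withr::with_seed(as.integer(seed),
                            matrix(stats::runif(length(C), 0, 1e-9), nrow(C)))
    C <- C + jit
  }
  C[C <= 0] <- 1e-12; S[S <= 0] <- 1e-12  # strictly feasible start
  nx <- sqrt(sum(xs^2))
  prev_rec <- C %*% S
  converged <- FALSE
  change <- NA_real_
  it <- 0L
  for (it in seq_len(max_iter)) {
    C <- t(nnls_multi(t(S), t(xs)))
    # guard against dead components (all-zero rows make the LS singular)
    dead <- colSums(C) == 0
    if (any(dead)) C[, dead] <- 1e-12
    S <- nnls_multi(C, xs)
    dead <- rowSums(S) == 0
    if (any(dead)) S[dead, ] <- 1e-12
    rec <- C %*% S
    change <- sqrt(sum((rec - prev_rec)^2)) / max(nx, .Machine$double.eps)
    prev_rec <- rec
    if (change < tol) { converged <- TRUE; break }
  }
  # order by total score mass; normalize spectra to unit maximum
  mass <- colSums(C) * apply(S, 1L, max)
  ord <- order(mass, decreasing = TRUE)
  C <- C[, ord, drop = FALSE]; S <- S[ord, , drop = FALSE]
  for (j in seq_len(n_components)) {
    m <- max(S[j, ])
    if (m > 0) { S[j, ] <- S[j, ] / m; C[, j] <- C[, j] * m }
  }
  err <- sqrt(sum((xs - C %*% S)^2)) / max(nx, .Machine$double.eps)
  structure(list(C = C, S = S, n_components = as.integer(n_components),
                 converged = converged, iterations = it,
                 final_change = change, reconstruction_error = err,
                 row_shifts = shifts),
            class = "mcr_model")
}

#' Map curve-resolution components to container materials
#'
#' Matches each recovered component spectrum to the reference container
#' profile with which it has the highest cosine similarity, without reusing a
#' material (greedy best-first assignment).
#'
#' @param mcr A [fit_mcr()] model.
#' @param references Named list of reference profiles: numeric vectors on the
#'   same axis as the factored matrix.
#' @return Character vector, one material per component, plus cosine
#'   similarities as the `"cosine"` attribute.
#' @export
map_components <- function(mcr, references) {
  S <- mcr$S
  refm <- do.call(rbind, lapply(references, as.numeric))
  if (ncol(refm) != ncol(S)) {
    stop("map_components: references not on the factored axis", call. = FALSE)
  }
  cosm <- matrix(0, nrow(S), nrow(refm),
                 dimnames = list(NULL, names(references)))
  for (i in seq_len(nrow(S))) {
    for (j in seq_len(nrow(refm))) {
      cosm[i, j] <- cosine_similarity(S[i, ], refm[j, ])
    }
  }
  assign <- rep(NA_character_, nrow(S))
  sims <- rep(NA_real_, nrow(S))
  free_c <- seq_len(nrow(S)); free_m <- seq_len(nrow(refm))
  while (length(free_c) && length(free_m)) {
    sub <- cosm[free_c, free_m, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    ci <- free_c[ij[1L]]; mi <- free_m[ij[2L]]
    assign[ci] <- colnames(cosm)[mi]
    sims[ci] <- cosm[ci, mi]
    free_c <- setdiff(free_c, ci); free_m <- setdiff(free_m, mi)
  }
  attr(assign, "cosine") <- sims
  assign
}

#' Assign a container material to one sample
#'
#' The material of the component with the largest score for that sample; the
#' winning score and the margin over the runner-up are reported. An all-zero
#' score row (or an exact tie) yields `"indeterminate"`.
#'
#' @param mcr A [fit_mcr()] model.
#' @param sample_index Row index into the score matrix.
#' @param material_map Component-to-material labels, as from
#'   [map_components()].
#' @return A list with `material`, `score`, `margin`.
#' @export
assign_container <- function(mcr, sample_index, material_map) {
  sc <- mcr$C[sample_index, ]
  if (all(sc <= 0)) {
    return(list(material = "indeterminate", score = 0, margin = 0))
  }
  ord <- order(sc, decreasing = TRUE)
  margin <- sc[ord[1L]] - if (length(sc) > 1L) sc[ord[2L]] else 0
  if (margin == 0) {
    return(list(material = "indeterminate", score = sc[ord[1L]], margin = 0))
  }
  list(material = material_map[ord[1L]], score = sc[ord[1L]], margin = margin)
}

# Cosine similarity between two vectors (0 when either is all-zero).
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
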