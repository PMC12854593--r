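test_that("PCA reproduces a brute-force covariance eigendecomposition", {
  x <- withr::with_seed(21, matrix(rnorm(10 * 20), 10, 20))
  p <- fit_pca(x, 9)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  expect_lt(max(abs(p$sdev^2 - ev$values[1:9])), 1e-8)
  for (j in 1:9) {
    v <- ev$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v        # align with the package's sign convention
    expect_lt(max(abs(p$loadings[, j] - v)), 1e-7)
  }
  # orthonormal loadings; variance fractions conserved over full rank
  g <- crossprod(p$loadings)
  expect_lt(max(abs(g - diag(9))), 1e-8)
  expect_lt(abs(sum(p$explained_variance) - 1), 1e-9)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
})

test_that("rank-1 data put all variance on PC1", {
  base <- withr::with_seed(3, rnorm(15))
  x <- outer(seq(1, 2, length.out = 6), base)
  p <- fit_pca(x, 3)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)
  expect_error(fit_pca(x, 10), "exceeds")
})

test_that("projection is centred and reconstruction is complete", {
  x <- withr::with_seed(7, matrix(rnorm(12 * 8), 12, 8))
  p <- fit_pca(x, 8)
  expect_lt(max(abs(pca_project(p, p$mean))), 1e-10)
  sc <- pca_project(p, x)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  expect_lt(max(abs(pca_reconstruct(p, sc) - x)), 1e-8)
})

test_that("confidence ellipses have chi-square coverage and PSD guards", {
  pts <- withr::with_seed(11, matrix(rnorm(4000), ncol = 2))
  e <- confidence_ellipse(pts, 0.95)
  expect_lt(abs(e$radii[1] - e$radii[2]) / e$radii[1], 0.1)  # isotropy
  frac <- mean(ellipse_contains(e, pts))
  expect_gte(frac, 0.93); expect_lte(frac, 0.97)
  dup <- matrix(rep(c(1, 2), each = 5), ncol = 2)
  ed <- confidence_ellipse(dup)
  expect_true(all(ed$radii == 0))
  expect_error(confidence_ellipse(pts[1:2, ]), ">= 3 points")
})

test_that("KNN matches an exhaustive scan and breaks ties deterministically", {
  withr::with_seed(31, {
    train <- matrix(rnorm(50 * 3), 50, 3)
    labels <- sample(c("a", "b", "c", "d"), 50, replace = TRUE)
    queries <- matrix(rnorm(20 * 3), 20, 3)
  })
  model <- fit_knn(train, labels, k = 4)
  brute <- function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    nn <- order(d)[1:4]
    nl <- labels[nn]
    votes <- table(nl)
    top <- names(votes)[votes == max(votes)]
    cm <- vapply(top, function(cl) mean(d[nn][nl == cl]), numeric(1))
    top[order(cm, top)][1]
  }
  for (i in 1:20) {
    expect_equal(knn_classify(model, queries[i, ])$nearest_label,
                 brute(queries[i, ]))
  }
  # an exact training point whose class fills the neighbourhood wins
  tight <- rbind(matrix(0.01 * rnorm(8), 4, 2), matrix(5 + rnorm(8), 4, 2))
  mt <- fit_knn(tight, rep(c("x", "y"), each = 4), k = 4)
  expect_equal(knn_classify(mt, tight[1, ])$label, "x")
  # engineered 2-2 tie: class with smaller mean neighbour distance wins
  pts <- rbind(c(-1, 0), c(-1.1, 0), c(1.5, 0), c(1.6, 0),
               c(9, 9), c(-9, 9))
  m2 <- fit_knn(pts, c("near", "near", "far", "far", "pad", "pad"), k = 4)
  r <- knn_classify(m2, c(0, 0))
  expect_equal(r$nearest_label, "near")
  expect_true(is.finite(r$margin))
  expect_error(knn_classify(fit_knn(pts, rep("a", 6), k = 7)), "outside")
})

test_that("KNN agrees with class::knn where no ties are involved", {
  skip_if_not_installed("class")
  withr::with_seed(13, {
    train <- matrix(rnorm(60 * 4), 60, 4)
    labels <- rep(c("p", "q", "r"), each = 20)
    centers <- matrix(c(0, 0, 0, 0, 4, 4, 4, 4, -4, 4, -4, 4), 3, 4, byrow = TRUE)
    train <- train + centers[rep(1:3, each = 20), ]
    queries <- centers + 0.2 * matrix(rnorm(12), 3, 4)
  })
  model <- fit_knn(train, labels, k = 4)
  ours <- vapply(1:3, function(i) knn_classify(model, queries[i, ])$nearest_label, "")
  ref <- as.character(class::knn(train, queries, factor(labels), k = 4))
  expect_equal(ours, ref)
})

test_that("the out-of-set threshold rejects distant queries only", {
  withr::with_seed(41, {
    train <- matrix(rnorm(40 * 2), 40, 2)
  })
  model <- fit_knn(train, rep(c("a", "b"), 20), k = 4)
  expect_equal(model$threshold,
               unname(stats::quantile(model$loo_distances, 0.99)))
  inside <- knn_classify(model, train[3, ])
  expect_false(inside$out_of_set)
  far <- knn_classify(model, c(50, 50))
  expect_true(far$out_of_set)
  expect_equal(far$label, "OUT_OF_SET")
  expect_true(far$nearest_label %in% c("a", "b"))
})

test_that("vectorized non-negative least squares matches the reference solver", {
  skip_if_not_installed("pracma")
  withr::with_seed(17, {
    for (rep in 1:5) {
      A <- matrix(runif(40 * 6), 40, 6)
      B <- matrix(rnorm(40 * 7), 40, 7)
      X <- nnls_multi(A, B)
      expect_true(all(X >= 0))
      ref <- vapply(1:7, function(j) pracma::lsqnonneg(A, B[, j])$x,
                    numeric(6))
      expect_lt(max(abs(X - ref)), 1e-6)
    }
  })
})

test_that("curve resolution recovers an exact non-negative factorization", {
  withr::with_seed(4, {
    Ct <- matrix(rexp(30 * 3), 30, 3)
  })
  St <- t(vapply(1:3, function(k) {
    pseudo_voigt(1:500, 100 + 150 * k, 40) +
      0.3 * pseudo_voigt(1:500, 50 + 170 * k, 30)
  }, numeric(500)))
  x <- Ct %*% St
  m <- fit_mcr(x, 3, tol = 1e-10)
  expect_true(m$converged)
  expect_lt(m$reconstruction_error, 1e-3)
  expect_true(all(m$S >= 0) && all(m$C >= 0))
  for (k in 1:3) {
    best <- max(vapply(1:3, function(j) cosine(m$S[j, ], St[k, ]), numeric(1)))
    expect_gt(best, 0.99)
  }
  # rank-1 exact recovery
  r1 <- matrix(runif(10), 10, 1) %*% matrix(runif(20), 1, 20)
  m1 <- fit_mcr(r1, 1, tol = 1e-12)
  expect_lt(m1$reconstruction_error, 1e-6)
  expect_error(fit_mcr(r1, 15), "exceeds")
})

test_that("alternating least squares never increases the reconstruction error", {
  withr::with_seed(6, {
    x <- matrix(rexp(20 * 60), 20, 60)
  })
  errs <- vapply(c(1, 2, 5, 10, 25, 60), function(it) {
    fit_mcr(x, 4, tol = 0, max_iter = it)$reconstruction_error
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  unconverged <- fit_mcr(x, 4, tol = 1e-14, max_iter = 3)
  expect_false(unconverged$converged)   # flag, not an exception
})

test_that("container assignment follows the dominant component with tie guard", {
  S <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  mcr <- structure(list(C = rbind(c(3, 1), c(0.5, 2), c(1, 1), c(0, 0)),
                        S = S, n_components = 2L), class = "mcr_model")
  map <- c("glass", "plastic")
  expect_equal(assign_container(mcr, 1, map)$material, "glass")
  expect_equal(assign_container(mcr, 2, map)$material, "plastic")
  expect_equal(assign_container(mcr, 3, map)$material, "indeterminate")
  expect_equal(assign_container(mcr, 4, map)$material, "indeterminate")
  refs <- list(glass = c(1, 0, 0, 0), plastic = c(0, 1, 0, 0))
  assigned <- map_components(mcr, refs)
  expect_equal(as.character(assigned), c("glass", "plastic"))
})
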