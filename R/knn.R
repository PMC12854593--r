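#' Build a k-nearest-neighbour classifier in PCA space
#'
#' Stores calibration scores and labels for Euclidean-distance majority-vote
#' classification (default k = 4) and calibrates the out-of-set distance
#' threshold: the given percentile (default 99%) of the leave-one-out mean
#' k-neighbour distances of the training points. A query whose mean
#' k-neighbour distance exceeds this threshold is outside the calibration
#' support and is labelled `"OUT_OF_SET"`.
#'
#' @param scores Training score matrix (rows = calibration replicates).
#' @param labels Character vector of class labels, one per row.
#' @param k Neighbours (default 4; must be `<= nrow(scores)`).
#' @param out_of_set_percentile Percentile of training leave-one-out mean
#'   neighbour distances used as the rejection threshold (default 0.99).
#' @return A list of class `knn_model` with the training data, `k`,
#'   `threshold`, and the leave-one-out distance distribution `loo_distances`.
#' @export
fit_knn <- function(scores, labels, k = 4L, out_of_set_percentile = 0.99) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels))
  if (k < 1L || k > nrow(scores)) {
    stop(sprintf("fit_knn: k = %d outside [1, %d]", k, nrow(scores)),
         call. = FALSE)
  }
  model <- structure(list(scores = scores, labels = labels, k = as.integer(k),
                          threshold = Inf, loo_distances = NULL,
                          out_of_set_percentile = out_of_set_percentile),
                     class = "knn_model")
  loo <- vapply(seq_len(nrow(scores)), function(i) {
    knn_classify(model, scores[i, ], exclude = i)$mean_distance
  }, numeric(1))
  model$loo_distances <- loo
  model$threshold <- as.numeric(stats::quantile(loo, out_of_set_percentile))
  model
}

#' Classify a query point by k nearest neighbours
#'
#' Majority vote among the k nearest training points by Euclidean distance.
#' Ties are broken by the smallest mean distance to the tied class's
#' neighbours, then lexicographically; the rules are deterministic. Distances
#' and the vote table are returned for downstream thresholding; the label
#' becomes `"OUT_OF_SET"` when the mean neighbour distance exceeds the model's
#' calibrated threshold (the underlying nearest-class vote is still reported
#' in `nearest_label`).
#'
#' @param model A [fit_knn()] model.
#' @param query Numeric vector (one point in the model's PC space).
#' @param exclude Optional training-row indices excluded from the neighbour
#'   search (used for leave-one-out).
#' @return A list with `label`, `nearest_label`, `mean_distance` (mean of the
#'   k neighbour distances), `neighbor_distances`, `neighbor_labels`, `votes`,
#'   `margin` (relative mean-distance gap between the runner-up class's
#'   neighbours and the winner's; `Inf` for a unanimous vote), and
#'   `out_of_set`.
#' @export
knn_classify <- function(model, query, exclude = integer(0)) {
  stopifnot(inherits(model, "knn_model"))
  if (nrow(model$scores) == 0L) stop("knn_classify: empty model", call. = FALSE)
  query <- as.numeric(query)
  keep <- setdiff(seq_len(nrow(model$scores)), exclude)
  if (length(keep) < model$k) {
    stop("knn_classify: fewer candidate points than k", call. = FALSE)
  }
  d <- sqrt(colSums((t(model$scores[keep, , drop = FALSE]) - query)^2))
  ord <- order(d, keep)                  # index tie-break: deterministic
  nn <- ord[seq_len(model$k)]
  nd <- d[nn]
  nl <- model$labels[keep][nn]
  votes <- sort(table(nl), decreasing = TRUE)
  top <- names(votes)[votes == max(votes)]
  class_mean <- vapply(top, function(cl) mean(nd[nl == cl]), numeric(1))
  top <- top[order(class_mean, top)]     # closest mean, then lexicographic
  winner <- top[1L]
  others <- setdiff(unique(nl), winner)
  margin <- if (length(others) == 0L) Inf else {
    dw <- mean(nd[nl == winner])
    do <- min(vapply(others, function(cl) mean(nd[nl == cl]), numeric(1)))
    (do - dw) / max(mean(nd), .Machine$double.eps)
  }
  mean_d <- mean(nd)
  oos <- mean_d > model$threshold
  list(label = if (oos) "OUT_OF_SET" else winner,
       nearest_label = winner,
       mean_distance = mean_d,
       neighbor_distances = nd,
       neighbor_labels = nl,
       votes = votes,
       margin = margin,
       out_of_set = oos)
}
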