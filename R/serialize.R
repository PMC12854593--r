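#' Save a calibration model to a portable JSON archive
#'
#' Serializes the axis, both representations' PCA mean/loadings/variances,
#' selected PCs and scalings, training scores and labels, KNN settings and
#' out-of-set thresholds, and the per-class reference spectra into a single
#' human-readable JSON document (numbers at full double precision). The
#' layout is a flat object whose keys mirror the `sors_calibration` fields;
#' see [load_calibration()].
#'
#' @param calibration A [calibrate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "sors_calibration"))
  pack <- function(m) {
    list(pca = list(mean = m$pca$mean,
                    loadings = m$pca$loadings,
                    explained_variance = m$pca$explained_variance,
                    sdev = m$pca$sdev,
                    n_components = m$pca$n_components),
         selected = m$selected,
         pc_scale = m$pc_scale,
         f_statistic = m$f_statistic,
         knn = list(scores = m$knn$scores,
                    labels = m$knn$labels,
                    k = m$knn$k,
                    threshold = m$knn$threshold,
                    loo_distances = m$knn$loo_distances,
                    out_of_set_percentile = m$knn$out_of_set_percentile),
         references = lapply(m$references, `[[`, "intensity"))
  }
  obj <- list(format = "sorsid-calibration-1",
              axis = calibration$axis,
              labels = calibration$labels,
              training_container = calibration$training_container,
              models = lapply(calibration[c("plain",
                                            names(container_library()))],
                              pack))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a calibration model saved by [save_calibration()]
#'
#' @param path JSON archive path.
#' @param config A [run_config()] to attach (classification-time tunables are
#'   not part of the archive).
#' @return A `sors_calibration`.
#' @export
load_calibration <- function(path, config = run_config()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "sorsid-calibration-1")) {
    stop("load_calibration: unrecognized archive format", call. = FALSE)
  }
  unpack <- function(m) {
    pca <- structure(list(mean = m$pca$mean,
                          loadings = as.matrix(m$pca$loadings),
                          explained_variance = m$pca$explained_variance,
                          sdev = m$pca$sdev,
                          n_components = as.integer(m$pca$n_components)),
                     class = "pca_model")
    knn <- structure(list(scores = as.matrix(m$knn$scores),
                          labels = m$knn$labels,
                          k = as.integer(m$knn$k),
                          threshold = m$knn$threshold,
                          loo_distances = m$knn$loo_distances,
                          out_of_set_percentile = m$knn$out_of_set_percentile),
                     class = "knn_model")
    refs <- lapply(m$references, function(i) {
      spectrum(obj$axis, i, list(channel = "processed"))
    })
    list(pca = pca, selected = as.integer(m$selected),
         pc_scale = m$pc_scale, f_statistic = m$f_statistic,
         knn = knn, references = refs, scores = NULL)
  }
  structure(c(lapply(obj$models, unpack),
              list(axis = obj$axis, labels = obj$labels, config = config,
                   training_container = obj$training_container)),
            class = "sors_calibration")
}
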