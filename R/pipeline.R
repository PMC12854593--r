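#' Run configuration
#'
#' Bundles every tunable of the end-to-end pipeline.
#'
#' @param preprocess A [preprocess_config()].
#' @param pca_variance Build the candidate-PC pool from the smallest number
#'   of PCs reaching this cumulative explained-variance fraction (default
#'   0.9999)...
#' @param pca_max_components ...capped at this many pool PCs (default 40).
#' @param pca_select From the pool, retain this many PCs ranked by
#'   between-class F statistic on the calibration labels (default 8); each
#'   retained PC is scaled by its pooled within-class standard deviation
#'   before distances are computed, so stable class-discriminating directions
#'   are not drowned by within-class concentration variability.
#' @param knn_k Neighbours for classification (default 4).
#' @param out_of_set_percentile Training leave-one-out distance percentile
#'   used as the rejection threshold (default 0.99).
#' @param ambiguity_margin A query whose relative nearest-class margin (see
#'   [knn_classify()]) falls below this fraction is flagged near-threshold
#'   (default 0.10).
#' @param mcr_components Components for container resolution (default 6).
#' @param residual_threshold Residual-band prominence threshold in units of
#'   the robust (MAD-based) residual noise sd (default 5).
#' @return A list of class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       pca_variance = 0.9999, pca_max_components = 40L,
                       pca_select = 8L,
                       knn_k = 4L, out_of_set_percentile = 0.99,
                       ambiguity_margin = 0.10, mcr_components = 6L,
                       residual_threshold = 5) {
  stopifnot(pca_variance > 0, pca_variance <= 1, pca_max_components >= 1,
            pca_select >= 1, pca_select <= pca_max_components,
            knn_k >= 1, out_of_set_percentile > 0, out_of_set_percentile <= 1,
            ambiguity_margin >= 0, mcr_components >= 1, residual_threshold > 0)
  structure(list(preprocess = preprocess, pca_variance = pca_variance,
                 pca_max_components = as.integer(pca_max_components),
                 pca_select = as.integer(pca_select),
                 knn_k = as.integer(knn_k),
                 out_of_set_percentile = out_of_set_percentile,
                 ambiguity_margin = ambiguity_margin,
                 mcr_components = as.integer(mcr_components),
                 residual_threshold = residual_threshold),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Sections `preprocess:` and `pipeline:` mirror the arguments of
#' [preprocess_config()] and [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_run_config: the 'yaml' package is required", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  known <- c("preprocess", "pipeline")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("read_run_config: unknown section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pp_args <- raw$preprocess %||% list()
  bad <- setdiff(names(pp_args), names(formals(preprocess_config)))
  if (length(bad)) {
    stop("read_run_config: unknown preprocess key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pl_args <- raw$pipeline %||% list()
  bad <- setdiff(names(pl_args), setdiff(names(formals(run_config)), "preprocess"))
  if (length(bad)) {
    stop("read_run_config: unknown pipeline key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pl_args$preprocess <- do.call(preprocess_config, lapply(pp_args, unlist))
  do.call(run_config, pl_args)
}

#' Calibrate the fluid classifier
#'
#' Processes every calibration measurement through the differential chain and
#' fits PCA on the processed fluid spectra. From the pool of PCs reaching the
#' configured cumulative variance, the `pca_select` PCs with the largest
#' between-class F statistic (one-way analysis of variance of the scores
#' against the class labels) are retained as the classification space, and
#' each is scaled by its pooled within-class standard deviation; the KNN
#' model (with its out-of-set threshold) is built on these scaled scores.
#' Per-class mean reference spectra are stored for residual analysis.
#'
#' @param measurements List of `sors_measurement` objects.
#' @param labels Class label per measurement.
#' @param config A [run_config()].
#' Because sharp-container (polymer) measurements are classified in a
#' deflated representation (see [process_measurement()]), the calibration
#' holds one classifier per representation, built from the same calibration
#' measurements: `plain` plus one per container material. A query is matched
#' against the classifier of its own representation.
#'
#' @return A list of class `sors_calibration` with element `plain` and one
#'   element per container material (each a classifier: `pca`, `selected` PC
#'   indices, `pc_scale`, `f_statistic`, `knn`, `references`), plus `axis`,
#'   `labels`, `config`.
#' @export
calibrate <- function(measurements, labels, config = run_config()) {
  labels <- as.character(labels)
  stopifnot(length(measurements) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("calibrate: need >= 2 classes", call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts < 2L)) {
    warning("calibrate: class(es) with < 2 replicates included: ",
            paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  pairs <- lapply(measurements, process_measurement, config = config$preprocess)
  models <- list(
    plain = build_classifier(lapply(pairs, `[[`, "fluid_spectrum"),
                             labels, config))
  for (mat in names(pairs[[1L]]$fluid_deflated)) {
    models[[mat]] <- build_classifier(
      lapply(pairs, function(p) p$fluid_deflated[[mat]]), labels, config)
  }
  matches <- vapply(pairs, `[[`, "", "container_match")
  structure(c(models,
              list(axis = pairs[[1L]]$fluid_spectrum$wavenumber,
                   labels = labels, config = config,
                   training_container = names(sort(table(matches),
                                                   decreasing = TRUE))[1L])),
            class = "sors_calibration")
}

# One classification model: PCA pool, F-ranked PC selection, within-class
# scaling, KNN with out-of-set threshold, class-mean reference spectra.
build_classifier <- function(fluids, labels, config) {
  x <- spectra_matrix(fluids)
  kmax <- min(nrow(x) - 1L, ncol(x), config$pca_max_components)
  pca_full <- fit_pca(x, min(nrow(x) - 1L, ncol(x)))
  cum <- cumsum(pca_full$explained_variance)
  ncomp <- min(which(cum >= config$pca_variance - 1e-12)[1L] %||% kmax, kmax)
  if (is.na(ncomp)) ncomp <- kmax
  pca <- fit_pca(x, ncomp)
  scores <- pca_project(pca, x)
  grp <- factor(labels)
  fstat <- apply(scores, 2L, function(s) {
    summary(stats::aov(s ~ grp))[[1L]]$`F value`[1L]
  })
  nsel <- min(config$pca_select, ncomp)
  selected <- sort(order(fstat, decreasing = TRUE)[seq_len(nsel)])
  within_sd <- apply(scores[, selected, drop = FALSE], 2L, function(s) {
    sqrt(mean(tapply(s, grp, stats::var), na.rm = TRUE))
  })
  pc_scale <- 1 / pmax(within_sd, .Machine$double.eps)
  scaled <- sweep(scores[, selected, drop = FALSE], 2L, pc_scale, `*`)
  knn <- fit_knn(scaled, labels, k = config$knn_k,
                 out_of_set_percentile = config$out_of_set_percentile)
  refs <- lapply(split(seq_along(fluids), labels), function(idx) {
    average_replicates(fluids[idx])
  })
  list(pca = pca, selected = selected, pc_scale = pc_scale,
       f_statistic = fstat, knn = knn, references = refs, scores = scores)
}

#' Map spectra into a calibration's classification space
#'
#' Projects processed spectra into the calibration PCA of the requested
#' representation, keeps the selected discriminant PCs, and applies the
#' within-class scaling — the coordinates in which the KNN model measures
#' Euclidean distance.
#'
#' @param calibration A [calibrate()] result.
#' @param x Intensity matrix (or vector) on the calibration axis.
#' @param representation `"plain"` or a container-material name.
#' @return Scaled score matrix.
#' @export
classification_scores <- function(calibration, x, representation = "plain") {
  m <- calibration[[representation]]
  if (is.null(m)) {
    stop("classification_scores: unknown representation ", representation,
         call. = FALSE)
  }
  sc <- pca_project(m$pca, x)
  sweep(sc[, m$selected, drop = FALSE], 2L, m$pc_scale, `*`)
}

#' @export
print.sors_calibration <- function(x, ...) {
  cat(sprintf(paste0("<sors_calibration: %d classes, %d training spectra, ",
                     "%d of %d PCs retained (F-ranked), k = %d>\n"),
              length(x$plain$references), nrow(x$plain$knn$scores),
              length(x$plain$selected), x$plain$pca$n_components,
              x$plain$knn$k))
  invisible(x)
}

# Excipient group of a class label, for the shared-excipient ambiguity rule.
class_excipients <- function(labels) {
  reg <- tryCatch(calibration_recipes(paste0("C", 1:20)), error = function(e) list())
  vapply(labels, function(l) {
    if (!is.null(reg[[l]])) reg[[l]]$excipient else NA_character_
  }, "")
}

#' Classify one sample record
#'
#' The primary label comes from the replicate-averaged processed fluid
#' spectrum (re-normalized by SNV after averaging); each replicate is also
#' classified separately to detect location-dependent ambiguity. The sample
#' is classified in the representation matching its own container material
#' (see [process_measurement()]), falling back to the plain representation
#' when that material is the one the calibration itself was measured
#' through — then there is no container mismatch to deflate. The outcome
#' flag follows, in order of precedence: `FAILED` when the averaged spectrum
#' is rejected as `OUT_OF_SET`, disagrees with a supplied truth label, or the
#' measurement has no zero/offset contrast; `AMBIGUOUS` when replicate labels
#' disagree (the notes record whether they share a main excipient group) or
#' the vote margin is below the configured near-threshold fraction; `MATCH`
#' otherwise.
#'
#' @param record A [sample_record()].
#' @param calibration A [calibrate()] result.
#' @param truth Optional true class label (`"OUT_OF_SET"` allowed).
#' @return A list of class `classification_result`: `sample_id`,
#'   `predicted_fluid`, `per_replicate_labels`, `outcome_flag`,
#'   `mean_distance`, `margin`, `notes`, `residual_bands` (bands left after
#'   subtracting the assigned class reference, see [residual_analysis()]),
#'   plus the processed averaged fluid spectrum and per-replicate container
#'   spectra for downstream stages.
#' @export
classify_sample <- function(record, calibration, truth = NULL) {
  stopifnot(inherits(record, "sample_record"),
            inherits(calibration, "sors_calibration"))
  config <- calibration$config
  pairs <- lapply(record$measurements, process_measurement,
                  config = config$preprocess)
  degenerate <- vapply(pairs, `[[`, logical(1), "degenerate")
  if (all(degenerate)) {
    return(structure(list(sample_id = record$sample_id,
                          predicted_fluid = NA_character_,
                          per_replicate_labels = rep(NA_character_, length(pairs)),
                          outcome_flag = "FAILED",
                          mean_distance = NA_real_, margin = NA_real_,
                          notes = "no offset contrast",
                          representation = "plain",
                          fluid_spectrum = NULL,
                          container_spectra = lapply(pairs, `[[`, "container_spectrum"),
                          truth = truth),
                     class = "classification_result"))
  }
  pairs_ok <- pairs[!degenerate]
  mm <- vapply(pairs_ok, `[[`, "", "container_match")
  repr <- names(sort(table(mm), decreasing = TRUE))[1L]
  # measured through the same container family as the calibration: nothing
  # to deflate, use the full-information representation
  if (identical(repr, calibration$training_container)) repr <- "plain"
  model <- calibration[[repr]]
  fluids <- lapply(pairs_ok, function(p) {
    if (repr == "plain") p$fluid_spectrum else p$fluid_deflated[[repr]]
  })
  avg <- snv(average_replicates(fluids), config$preprocess$snv_epsilon)
  main <- knn_classify(model$knn,
                       classification_scores(calibration, avg$intensity, repr))
  rep_labels <- vapply(fluids, function(f) {
    knn_classify(model$knn,
                 classification_scores(calibration, f$intensity, repr))$label
  }, "")
  notes <- character(0)
  if (any(degenerate)) {
    notes <- c(notes, sprintf("%d degenerate replicate(s) dropped",
                              sum(degenerate)))
  }
  flag <- "MATCH"
  disagree <- length(unique(rep_labels)) > 1L
  if (disagree) {
    exc <- class_excipients(setdiff(unique(rep_labels), "OUT_OF_SET"))
    shared <- length(unique(stats::na.omit(exc))) == 1L && !anyNA(exc)
    notes <- c(notes, sprintf("replicates disagree (%s excipient group)",
                              if (shared) "shared" else "mixed"))
    flag <- "AMBIGUOUS"
  }
  if (is.finite(main$margin) && main$margin < config$ambiguity_margin) {
    notes <- c(notes, "near-threshold vote margin")
    flag <- "AMBIGUOUS"
  }
  if (main$out_of_set) {
    notes <- c(notes, "beyond calibration distance threshold")
    flag <- "FAILED"
  } else if (!is.null(truth) && !is.na(truth) && main$label != truth) {
    notes <- c(notes, sprintf("truth mismatch (expected %s)", truth))
    flag <- "FAILED"
  }
  bands <- if (main$label %in% names(model$references)) {
    residual_analysis(avg, model$references[[main$label]],
                      config$residual_threshold)$bands
  } else {
    data.frame(center = numeric(0), prominence = numeric(0),
               height = numeric(0))
  }
  structure(list(sample_id = record$sample_id,
                 predicted_fluid = main$label,
                 per_replicate_labels = rep_labels,
                 outcome_flag = flag,
                 mean_distance = main$mean_distance,
                 margin = main$margin,
                 notes = paste(notes, collapse = "; "),
                 residual_bands = bands,
                 representation = repr,
                 fluid_spectrum = avg,
                 container_spectra = lapply(pairs, `[[`, "container_spectrum"),
                 truth = truth),
            class = "classification_result")
}

#' Residual analysis against an assigned reference
#'
#' Subtracts the best least-squares fit `alpha * reference + beta` (scale
#' plus intercept, so a band's flat-offset correlation with the normalized
#' reference does not bias the scaling)
#' from the processed sample spectrum and reports residual bands: local
#' maxima whose prominence exceeds `threshold` times the robust residual
#' noise sd (median absolute deviation). Band centres are refined by
#' quadratic interpolation around the apex. An empty band list is a valid
#' result. Both inputs must be on a common axis in the same (SNV) domain.
#'
#' @param sample_spectrum,reference `sors_spectrum` objects on a common axis.
#' @param threshold Prominence threshold in noise-sd units (default 5).
#' @return A list with `bands` (data.frame: `center`, `prominence`,
#'   `height`), `residual` (`sors_spectrum`), `alpha`, `noise_sd`.
#' @export
residual_analysis <- function(sample_spectrum, reference, threshold = 5) {
  stopifnot(is_spectrum(sample_spectrum), is_spectrum(reference))
  if (!same_axis(sample_spectrum, reference)) {
    stop_axis_mismatch("residual_analysis")
  }
  s <- sample_spectrum$intensity; r <- reference$intensity
  rc <- r - mean(r)
  alpha <- sum((s - mean(s)) * rc) / max(sum(rc^2), .Machine$double.eps)
  beta <- mean(s) - alpha * mean(r)
  res <- s - alpha * r - beta
  sigma <- max(stats::mad(res), .Machine$double.eps)
  bands <- find_bands(sample_spectrum$wavenumber, res, threshold * sigma)
  list(bands = bands,
       residual = spectrum(sample_spectrum$wavenumber, res,
                           list(channel = "processed", layer = "residual")),
       alpha = alpha, noise_sd = sigma)
}

# Local maxima whose height above zero AND prominence exceed `min_prom`
# (the residual is zero-centred, so height is meaningful; requiring both
# suppresses noise-dip artifacts). Prominence of a peak is its
# height above the higher of the two deepest valleys separating it from
# higher ground (or from the trace edge). Centres refined by a quadratic fit
# through the apex and its neighbours.
find_bands <- function(wn, y, min_prom) {
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  out <- data.frame(center = numeric(0), prominence = numeric(0),
                    height = numeric(0))
  for (p in peaks) {
    h <- y[p]
    left <- if (p > 1L) {
      higher <- which(y[1:(p - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(y[lo:(p - 1L)])
    } else h
    right <- if (p < n) {
      higher <- which(y[(p + 1L):n] > h)
      hi <- if (length(higher)) p + min(higher) - 1L else n
      min(y[(p + 1L):hi])
    } else h
    prom <- h - max(left, right)
    if (prom >= min_prom && h >= min_prom) {
      ctr <- wn[p]
      if (p > 1L && p < n) {            # quadratic apex refinement
        denom <- y[p - 1L] - 2 * y[p] + y[p + 1L]
        if (denom < 0) {
          delta <- 0.5 * (y[p - 1L] - y[p + 1L]) / denom
          ctr <- wn[p] + delta * (wn[p + 1L] - wn[p])
        }
      }
      out <- rbind(out, data.frame(center = ctr, prominence = prom, height = h))
    }
  }
  out[order(-out$prominence), , drop = FALSE]
}

#' Identify container materials across a cohort
#'
#' Stacks the per-sample reverse-SORS container spectra (replicates averaged),
#' min-shifts them, resolves them into non-negative components with
#' [fit_mcr()], maps components to materials by cosine match against rendered
#' reference container profiles, and assigns each sample the material of its
#' highest-scoring component.
#'
#' @param results List of [classify_sample()] results (>= `mcr_components`
#'   samples).
#' @param config A [run_config()].
#' @param axis Wavenumber axis of the container spectra.
#' @param seed Seed for the curve-resolution initialization jitter.
#' @return A list with `materials` (named character vector per sample),
#'   `mcr` (the fitted model), `component_materials`, `scores`.
#' @export
identify_containers <- function(results, config = run_config(),
                                axis = NULL, seed = NULL) {
  conts <- lapply(results, function(r) average_replicates(r$container_spectra))
  if (length(conts) < config$mcr_components) {
    stop(sprintf(paste0("identify_containers: %d samples < %d components; ",
                        "reduce mcr_components"),
                 length(conts), config$mcr_components), call. = FALSE)
  }
  x <- spectra_matrix(conts)
  axis <- axis %||% conts[[1L]]$wavenumber
  mcr <- fit_mcr(x, config$mcr_components, seed = seed)
  refs <- lapply(container_library(), function(cd) {
    render_component(cd, axis)$intensity
  })
  comp_mat <- map_components(mcr, refs)
  mats <- vapply(seq_along(results), function(i) {
    assign_container(mcr, i, comp_mat)$material
  }, "")
  names(mats) <- vapply(results, `[[`, "", "sample_id")
  list(materials = mats, mcr = mcr, component_materials = comp_mat,
       scores = mcr$C)
}

#' Build the cohort report
#'
#' One row per sample (id, expected label when given, predicted fluid,
#' container, outcome flag, residual evidence, distances) plus a summary with
#' counts and percentages of MATCH / AMBIGUOUS / FAILED (percentages to one
#' decimal). When a truth table is supplied a correctness column and a
#' fluid-class confusion summary are added.
#'
#' @param results List of [classify_sample()] results.
#' @param containers Optional [identify_containers()] result.
#' @param truth Optional truth data.frame (`sample_id`, `true_fluid`,
#'   `true_container`).
#' @return A list of class `sors_report` with `table` (data.frame), `summary`
#'   (named list), and optionally `confusion`.
#' @export
build_report <- function(results, containers = NULL, truth = NULL) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    data.frame(sample_id = r$sample_id,
               expected_label = r$truth %||% NA_character_,
               predicted_fluid = r$predicted_fluid,
               container = if (!is.null(containers))
                 unname(containers$materials[r$sample_id]) else NA_character_,
               outcome_flag = r$outcome_flag,
               mean_distance = r$mean_distance,
               margin = r$margin,
               residual_bands = if (is.null(r$residual_bands) ||
                                    nrow(r$residual_bands) == 0) "" else {
                 paste(sprintf("%.0f", r$residual_bands$center),
                       collapse = ";")
               },
               notes = r$notes,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  n <- nrow(tab)
  counts <- vapply(c("MATCH", "AMBIGUOUS", "FAILED"),
                   function(f) sum(tab$outcome_flag == f), numeric(1))
  pct <- round(100 * counts / n, 1)
  summary <- list(n = n, counts = as.list(counts), percent = as.list(pct))
  report <- list(table = tab, summary = summary)
  if (!is.null(truth)) {
    tr <- truth[match(tab$sample_id, truth$sample_id), , drop = FALSE]
    tab$true_fluid <- tr$true_fluid
    tab$fluid_correct <- ifelse(tr$true_fluid == "OUT_OF_SET",
                                tab$predicted_fluid == "OUT_OF_SET" |
                                  tab$outcome_flag == "FAILED",
                                tab$predicted_fluid == tr$true_fluid)
    if ("true_container" %in% names(tr) && !is.null(containers)) {
      tab$true_container <- tr$true_container
      tab$container_correct <- tab$container == tr$true_container
    }
    report$table <- tab
    report$confusion <- table(truth = tr$true_fluid,
                              predicted = tab$predicted_fluid)
  }
  class(report) <- "sors_report"
  report
}

#' @export
print.sors_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("SORS fluid-classification report: %d samples\n", s$n))
  for (f in names(s$counts)) {
    cat(sprintf("  %-9s %3d  (%.1f%%)\n", f, s$counts[[f]], s$percent[[f]]))
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Writes the machine-readable table as CSV and a human-readable text
#' summary next to it.
#'
#' @param report A [build_report()] result.
#' @param path CSV output path; the text summary gets extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  s <- report$summary
  writeLines(sprintf("SORS fluid-classification report: %d samples", s$n), con)
  for (f in names(s$counts)) {
    writeLines(sprintf("  %-9s %3d  (%.1f%%)", f, s$counts[[f]],
                       s$percent[[f]]), con)
  }
  invisible(path)
}

#' Run the full pipeline on a manifest
#'
#' Calibrates from (or reuses) a calibration model, classifies every sample
#' in the manifest, identifies containers, and builds the report.
#'
#' @param manifest_path Cohort manifest CSV (see [read_manifest()]).
#' @param calibration A [calibrate()] result.
#' @param config A [run_config()] (defaults to the calibration's).
#' @param truth Optional truth data.frame.
#' @param seed Seed forwarded to container resolution.
#' @return A `sors_report`.
#' @export
run_pipeline <- function(manifest_path, calibration, config = NULL,
                         truth = NULL, seed = NULL) {
  config <- config %||% calibration$config
  records <- read_manifest(manifest_path)
  results <- lapply(records, function(rec) {
    tr <- if (!is.null(truth)) {
      truth$true_fluid[match(rec$sample_id, truth$sample_id)]
    } else NULL
    classify_sample(rec, calibration, truth = tr)
  })
  containers <- identify_containers(results, config, seed = seed)
  build_report(results, containers, truth)
}

#' End-to-end synthetic demonstration
#'
#' Simulates a calibration set (classes C1-C13, 6 replicates each) and the
#' built-in 46-sample cohort, calibrates, classifies, identifies containers,
#' and reports. Everything is deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param config A [run_config()].
#' @param n_replicates Calibration replicates per class (default 6).
#' @param noise A [noise_model()].
#' @return A list with `report`, `calibration`, `containers`, `cohort`,
#'   `results`.
#' @export
run_demo <- function(seed = 1L, config = run_config(), n_replicates = 6,
                     noise = noise_model()) {
  seed <- as.integer(seed)
  cal_set <- generate_calibration_set(calibration_recipes(), n_replicates,
                                      noise = noise, seed = seed)
  calibration <- calibrate(cal_set$measurements, cal_set$labels, config)
  cohort <- generate_cohort(default_cohort_scenarios(), seed = seed + 1L,
                            noise = noise)
  results <- lapply(cohort$records, function(rec) {
    tr <- cohort$truth$true_fluid[match(rec$sample_id, cohort$truth$sample_id)]
    classify_sample(rec, calibration, truth = tr)
  })
  containers <- identify_containers(results, config, seed = seed)
  report <- build_report(results, containers, cohort$truth)
  list(report = report, calibration = calibration, containers = containers,
       cohort = cohort, results = results)
}
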