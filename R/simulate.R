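#' Two-layer mixing model
#'
#' Linear channel mixing for a container (surface) layer over a fluid
#' (subsurface) layer. The zero channel is container-dominated; moving the
#' collection point laterally enriches the subsurface contribution, so every
#' valid model must satisfy the enrichment invariant
#' `offset_fluid / offset_container > zero_fluid / zero_container`.
#'
#' @param zero_container,zero_fluid Container and fluid weights in the zero
#'   channel (defaults 0.8 and 0.2).
#' @param offset_container,offset_fluid Weights in the offset channel
#'   (defaults 0.3 and 0.7).
#' @return A list of class `mixing_model`.
#' @export
mixing_model <- function(zero_container = 0.8, zero_fluid = 0.2,
                         offset_container = 0.3, offset_fluid = 0.7) {
  stopifnot(zero_container >= 0, zero_fluid >= 0,
            offset_container >= 0, offset_fluid >= 0)
  r_zero <- zero_fluid / zero_container
  r_off <- offset_fluid / offset_container
  if (!(r_off > r_zero)) {
    stop("mixing_model: offset channel must be subsurface-enriched ",
         "(offset_fluid/offset_container > zero_fluid/zero_container)",
         call. = FALSE)
  }
  structure(list(zero_container = zero_container, zero_fluid = zero_fluid,
                 offset_container = offset_container,
                 offset_fluid = offset_fluid),
            class = "mixing_model")
}

#' Noise model for simulated channels
#'
#' Shot noise is Poisson on pseudo-counts (`intensity * shot_scale` counts,
#' rescaled back); read noise is additive Gaussian; drift is a random
#' low-order polynomial baseline emulating slowly varying fluorescence and
#' instrument drift; `fluid_fluorescence_scale` adds a broad emission envelope
#' to the fluid layer (aged, discoloured fluids fluoresce). All scales 0
#' disable noise entirely.
#'
#' @param shot_scale Pseudo-counts per unit intensity (default 20000; 0
#'   disables shot noise).
#' @param read_sd Additive Gaussian sd in intensity units (default 0.003).
#' @param drift_order,drift_sd Order and coefficient sd of the random
#'   polynomial drift (defaults 3 and 0.01).
#' @param fluid_fluorescence_scale Height of the broad fluid-fluorescence
#'   envelope (default 0.05).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(shot_scale = 20000, read_sd = 0.003,
                        drift_order = 3L, drift_sd = 0.01,
                        fluid_fluorescence_scale = 0.05) {
  stopifnot(shot_scale >= 0, read_sd >= 0, drift_sd >= 0, drift_order >= 0,
            fluid_fluorescence_scale >= 0)
  structure(list(shot_scale = shot_scale, read_sd = read_sd,
                 drift_order = as.integer(drift_order), drift_sd = drift_sd,
                 fluid_fluorescence_scale = fluid_fluorescence_scale),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_off <- function() noise_model(0, 0, 0L, 0, 0)

# Broad fluid-fluorescence envelope (fixed shape, scaled by the noise model).
fluid_fluorescence <- function(axis, scale) {
  if (scale <= 0) return(rep(0, length(axis)))
  scale * pseudo_voigt(axis, 1300, 900, 1, 0.95)
}

# Random polynomial drift on a normalized axis. Consumes RNG state.
drift_poly <- function(axis, order, sd) {
  if (sd <= 0 || order < 0) return(rep(0, length(axis)))
  u <- (axis - min(axis)) / diff(range(axis)) * 2 - 1
  coef <- stats::rnorm(order + 1L, 0, sd)
  drop(outer(u, 0:order, `^`) %*% coef)
}

# Apply shot + read noise to a clean channel; clamps at zero (photon counts).
apply_channel_noise <- function(clean, noise) {
  y <- clean
  if (noise$shot_scale > 0) {
    y <- stats::rpois(length(y), pmax(y, 0) * noise$shot_scale) / noise$shot_scale
  }
  if (noise$read_sd > 0) y <- y + stats::rnorm(length(y), 0, noise$read_sd)
  pmax(y, 0)
}

#' Simulate one paired zero/offset SORS measurement
#'
#' Renders the fluid (from its recipe) and the container profile on `axis`,
#' mixes them into the two channels with the [mixing_model()] weights, adds
#' fluid fluorescence, polynomial drift, shot and read noise, and returns the
#' pair with full ground truth in the metadata. Deterministic given `seed`.
#'
#' @param recipe A [fluid_recipe()].
#' @param container A container definition from [container_library()].
#' @param mixing A [mixing_model()].
#' @param noise A [noise_model()].
#' @param axis Wavenumber axis (default [default_axis()]).
#' @param library Component library.
#' @param sample_id,replicate_id Identifiers stored in the result.
#' @param seed Integer seed; when `NULL` the current RNG stream is consumed.
#' @param fractions Optional realized component fractions (see [mix_fluid()]).
#' @return A `sors_measurement` whose `ground_truth` holds the clean fluid and
#'   container profiles, the recipe label and the container material.
#' @export
simulate_measurement <- function(recipe, container, mixing = mixing_model(),
                                 noise = noise_model(), axis = default_axis(),
                                 library = default_component_library(),
                                 sample_id = recipe$label, replicate_id = "r1",
                                 seed = NULL, fractions = NULL) {
  run <- function() {
    fluid <- mix_fluid(recipe, library, axis, fractions = fractions)
    cont <- render_component(container, axis)
    cont$intensity <- cont$intensity * container$intensity_scale
    fl_int <- fluid$intensity +
      fluid_fluorescence(axis, noise$fluid_fluorescence_scale)
    zero_clean <- mixing$zero_container * cont$intensity +
      mixing$zero_fluid * fl_int
    offset_clean <- mixing$offset_container * cont$intensity +
      mixing$offset_fluid * fl_int
    zero_i <- apply_channel_noise(
      zero_clean + pmax(drift_poly(axis, noise$drift_order, noise$drift_sd), 0),
      noise)
    offset_i <- apply_channel_noise(
      offset_clean + pmax(drift_poly(axis, noise$drift_order, noise$drift_sd), 0),
      noise)
    truth <- list(fluid_label = recipe$label, container_material = container$material,
                  fluid_clean = fluid$intensity, container_clean = cont$intensity,
                  mixing = unclass(mixing))
    zero <- spectrum(axis, zero_i, list(sample_id = sample_id,
                                        replicate_id = replicate_id,
                                        channel = "zero"))
    offset <- spectrum(axis, offset_i, list(sample_id = sample_id,
                                            replicate_id = replicate_id,
                                            channel = "offset"))
    sors_measurement(sample_id, replicate_id, zero, offset,
                     ground_truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a labelled calibration set
#'
#' For each class recipe, simulates `n_replicates` measurements with
#' independent noise draws (and uniform jitter within any concentration
#' ranges). Deterministic given `seed`.
#'
#' @param class_recipes Named list of [fluid_recipe()] objects (>= 2 classes,
#'   unique labels).
#' @param n_replicates Replicates per class (>= 2).
#' @param container,mixing,noise,axis,library As in [simulate_measurement()].
#' @param seed Integer seed.
#' @return A list with `measurements` (list of `sors_measurement`) and
#'   `labels` (character vector, one per measurement).
#' @export
generate_calibration_set <- function(class_recipes, n_replicates = 6,
                                     container = container_library()[["soda_lime"]],
                                     mixing = mixing_model(),
                                     noise = noise_model(),
                                     axis = default_axis(),
                                     library = default_component_library(),
                                     seed = 1L) {
  stopifnot(length(class_recipes) >= 2, n_replicates >= 2)
  labels_in <- vapply(class_recipes, function(r) r$label, "")
  if (anyDuplicated(labels_in)) {
    stop("generate_calibration_set: duplicate class labels", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    measurements <- list()
    labels <- character(0)
    for (recipe in class_recipes) {
      for (j in seq_len(n_replicates)) {
        fr <- realize_fractions(recipe, jitter = 1)
        m <- simulate_measurement(recipe, container, mixing, noise, axis,
                                  library,
                                  sample_id = recipe$label,
                                  replicate_id = sprintf("rep%02d", j),
                                  seed = NULL, fractions = fr)
        measurements[[length(measurements) + 1L]] <- m
        labels <- c(labels, recipe$label)
      }
    }
    list(measurements = measurements, labels = labels)
  })
}

#' Define a cohort scenario
#'
#' One simulated "historic specimen": a fluid recipe (possibly absent from
#' the calibration set), a container material, a replicate count, and optional
#' perturbations (extra fluid fluorescence, additive interferent bands from
#' the specimen itself).
#'
#' @param sample_id Identifier (e.g. `"A7"`).
#' @param recipe A [fluid_recipe()].
#' @param container_material One of the [container_library()] materials.
#' @param n_replicates 2 or 3 (default 2).
#' @param truth_class True calibration class, or `"OUT_OF_SET"` for fluids
#'   not represented in the calibration set.
#' @param extra_fluorescence Additional fluid-fluorescence scale (default 0).
#' @param interferent_peaks Optional list of [peak_spec()] added to the fluid
#'   layer (residual specimen signals), heights relative to the unit fluid.
#' @return A list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(sample_id, recipe, container_material,
                            n_replicates = 2L, truth_class = recipe$label,
                            extra_fluorescence = 0, interferent_peaks = NULL) {
  stopifnot(n_replicates >= 1)
  if (!is.null(interferent_peaks)) {
    stopifnot(all(vapply(interferent_peaks, inherits, logical(1), "peak_spec")))
  }
  structure(list(sample_id = sample_id, recipe = recipe,
                 container_material = container_material,
                 n_replicates = as.integer(n_replicates),
                 truth_class = truth_class,
                 extra_fluorescence = extra_fluorescence,
                 interferent_peaks = interferent_peaks),
            class = "cohort_scenario")
}

#' Generate a synthetic historic cohort
#'
#' Simulates every scenario's replicates (independent noise; perturbations
#' applied as extra fluorescence and interferent bands in the fluid layer) and
#' returns the sample records together with a ground-truth table.
#' Deterministic given `seed`.
#'
#' @param scenarios List of [cohort_scenario()] objects.
#' @param seed Integer seed.
#' @param mixing,noise,axis,library As in [simulate_measurement()].
#' @return A list with `records` (list of [sample_record()]) and `truth`
#'   (data.frame with columns `sample_id`, `true_fluid`, `true_container`).
#' @export
generate_cohort <- function(scenarios, seed = 1L, mixing = mixing_model(),
                            noise = noise_model(), axis = default_axis(),
                            library = default_component_library()) {
  containers <- container_library()
  for (sc in scenarios) {
    if (!sc$container_material %in% names(containers)) {
      stop("generate_cohort: unknown container material ",
           sc$container_material, " in scenario ", sc$sample_id, call. = FALSE)
    }
  }
  withr::with_seed(as.integer(seed), {
    records <- list()
    truth <- data.frame(sample_id = character(0), true_fluid = character(0),
                        true_container = character(0),
                        stringsAsFactors = FALSE)
    for (sc in scenarios) {
      lib <- library
      recipe <- sc$recipe
      if (!is.null(sc$interferent_peaks)) {
        # interferent bands enter as a pseudo-component added to the fluid
        lib$`.interferent` <- component_def(".interferent", sc$interferent_peaks)
        comp <- recipe$components
        w <- 0.06                         # specimen-signal weight
        comp <- lapply(comp, function(f) f * (1 - w))
        comp$`.interferent` <- w
        recipe <- fluid_recipe(recipe$label, comp, recipe$excipient)
      }
      nz <- noise
      nz$fluid_fluorescence_scale <- nz$fluid_fluorescence_scale +
        sc$extra_fluorescence
      ms <- list()
      for (j in seq_len(sc$n_replicates)) {
        fr <- realize_fractions(recipe, jitter = 1)
        ms[[j]] <- simulate_measurement(recipe, containers[[sc$container_material]],
                                        mixing, nz, axis, lib,
                                        sample_id = sc$sample_id,
                                        replicate_id = sprintf("rep%02d", j),
                                        seed = NULL, fractions = fr)
      }
      records[[sc$sample_id]] <- sample_record(sc$sample_id, ms,
                                               expected_label = sc$truth_class)
      truth <- rbind(truth, data.frame(sample_id = sc$sample_id,
                                       true_fluid = sc$truth_class,
                                       true_container = sc$container_material,
                                       stringsAsFactors = FALSE))
    }
    list(records = records, truth = truth)
  })
}

#' Built-in 46-sample cohort scenario list
#'
#' Emulates a museum survey: 40 in-calibration samples drawn from classes
#' C1-C13 spread over all six container materials (a few with elevated
#' fluorescence or specimen-interferent bands but still in-set), plus 6
#' out-of-calibration fluids (Dowicil-based, formaldehyde + ethylene glycol,
#' phenoxetol + formaldehyde, Bouin's aqueous and alcoholic variants,
#' Kaiserling-like) that a classifier trained on C1-C13 must refuse.
#'
#' @param n_replicates Replicates per sample (default 2).
#' @return A list of 46 [cohort_scenario()] objects.
#' @export
default_cohort_scenarios <- function(n_replicates = 2L) {
  cal <- calibration_recipes(paste0("C", 1:13))
  ext <- calibration_recipes(paste0("C", 14:20))
  mats <- c("borosilicate", "soda_lime", "lead_glass", "pmma", "ldpe", "pp")
  # 40 in-set samples: cycle classes and containers deterministically
  classes <- rep(paste0("C", 1:13), length.out = 40)
  scen <- vector("list", 46)
  for (i in 1:40) {
    scen[[i]] <- cohort_scenario(sprintf("A%02d", i), cal[[classes[i]]],
                                 mats[(i - 1) %% 6 + 1],
                                 n_replicates = n_replicates)
  }
  oos <- list(
    fluid_recipe("dowicil_mix", list(dowicil = 0.05, water = 0.95), "dowicil"),
    fluid_recipe("form_eg_mix", list(formaldehyde = 0.04, ethylene_glycol = 0.30,
                                     water = 0.66), "glycol"),
    fluid_recipe("phenox_form", list(phenoxetol = 0.02, formaldehyde = 0.02,
                                     water = 0.96), "phenoxetol"),
    ext$C18, ext$C19, ext$C17)
  for (k in seq_along(oos)) {
    scen[[40 + k]] <- cohort_scenario(sprintf("A%02d", 40 + k), oos[[k]],
                                      mats[(k - 1) %% 6 + 1],
                                      n_replicates = n_replicates,
                                      truth_class = "OUT_OF_SET")
  }
  scen
}

#' Write a simulated cohort to disk
#'
#' Writes every zero/offset spectrum as a csv2col file plus a manifest CSV
#' (readable by [read_manifest()]) and a truth CSV.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (rec in cohort$records) {
    for (m in rec$measurements) {
      zp <- sprintf("%s_%s_zero.csv", m$sample_id, m$replicate_id)
      op <- sprintf("%s_%s_offset.csv", m$sample_id, m$replicate_id)
      write_spectrum(m$zero, file.path(dir, zp))
      write_spectrum(m$offset, file.path(dir, op))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = m$sample_id, replicate_id = m$replicate_id,
        zero_path = zp, offset_path = op,
        expected_label = rec$expected_label, offset_mm = m$offset_distance,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(mp)
}
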