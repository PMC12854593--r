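#' Pseudo-Voigt profile
#'
#' Linear mix of a Gaussian and a Lorentzian of common centre and FWHM:
#' `shape_mix * G + (1 - shape_mix) * L`, both unit-height.
#'
#' @param x Wavenumbers (cm^-1).
#' @param center Band centre (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param amplitude Peak height.
#' @param shape_mix Gaussian fraction in [0, 1] (1 = pure Gaussian).
#' @return Numeric vector of intensities.
#' @export
pseudo_voigt <- function(x, center, fwhm, amplitude = 1, shape_mix = 0.5) {
  stopifnot(fwhm > 0, amplitude >= 0, shape_mix >= 0, shape_mix <= 1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gamma <- fwhm / 2
  g <- exp(-(x - center)^2 / (2 * sigma^2))
  l <- gamma^2 / ((x - center)^2 + gamma^2)
  amplitude * (shape_mix * g + (1 - shape_mix) * l)
}

#' Define a peak
#'
#' @param center Band centre (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1).
#' @param amplitude Relative height.
#' @param shape_mix Gaussian fraction in [0, 1].
#' @param shifts Logical; `TRUE` marks a designated broad band whose centre
#'   moves with co-solute fraction when mixed (see [mix_fluid()]).
#' @return A list of class `peak_spec`.
#' @export
peak_spec <- function(center, fwhm, amplitude = 1, shape_mix = 0.5,
                      shifts = FALSE) {
  stopifnot(fwhm > 0, amplitude >= 0)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape_mix = shape_mix, shifts = shifts), class = "peak_spec")
}

#' Define a pure-component spectrum
#'
#' @param name Component name, unique within a library.
#' @param peaks List of [peak_spec()] objects (at least one).
#' @param shift_coefficient Centre shift, in cm^-1 per unit co-solute volume
#'   fraction, applied to peaks marked `shifts = TRUE` during mixing.
#' @return A list of class `component_def`.
#' @export
component_def <- function(name, peaks, shift_coefficient = 0) {
  if (length(peaks) < 1L) {
    stop("component_def: ", name, " needs at least one peak", call. = FALSE)
  }
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(list(name = name, peaks = peaks,
                 shift_coefficient = shift_coefficient),
            class = "component_def")
}

#' Render a component onto an axis
#'
#' Sums the component's pseudo-Voigt peaks and normalizes the result to unit
#' maximum. Warns when the axis does not cover every narrow peak's centre
#' +/- 3 FWHM (broad envelope bands, FWHM > 100 cm^-1, are exempt: their
#' tails extend past any finite window by construction).
#'
#' @param def A [component_def()] (or container definition with a peak list).
#' @param axis Numeric wavenumber axis.
#' @param center_shift Additive shift (cm^-1) applied to peaks marked
#'   `shifts = TRUE` before rendering.
#' @return A non-negative `sors_spectrum`, maximum 1.
#' @export
render_component <- function(def, axis, center_shift = 0) {
  peaks <- def$peaks
  narrow <- Filter(function(p) p$fwhm <= 100, peaks)
  lo <- min(vapply(narrow, function(p) p$center - 3 * p$fwhm, numeric(1)),
            Inf)
  hi <- max(vapply(narrow, function(p) p$center + 3 * p$fwhm, numeric(1)),
            -Inf)
  if (lo < min(axis) || hi > max(axis)) {
    warning(sprintf("render_component: axis does not cover %s peaks +/- 3 FWHM",
                    def$name), call. = FALSE)
  }
  y <- rep(0, length(axis))
  for (p in peaks) {
    ctr <- p$center + if (isTRUE(p$shifts)) center_shift else 0
    y <- y + pseudo_voigt(axis, ctr, p$fwhm, p$amplitude, p$shape_mix)
  }
  m <- max(y)
  if (m > 0) y <- y / m
  spectrum(axis, y, list(component = def$name, channel = "reference"))
}

#' Built-in pure-component library
#'
#' Pseudo-Voigt renderings of the solvents and additives found in historical
#' preservation fluids. Two band positions are anchored to well-known marker
#' bands (methanol C-O stretch near 1034 cm^-1; potassium acetate band near
#' 926 cm^-1); the remaining positions are plausible fixed constants chosen
#' for internal consistency of the simulator, not literature-grade line lists.
#' Water carries a designated broad bending band (1640 cm^-1) whose centre
#' shifts with co-solute fraction, emulating the concentration-dependent
#' OH-band shifts seen in ethanol-water mixtures.
#'
#' @return Named list of [component_def()] objects.
#' @export
default_component_library <- function() {
  lib <- list(
    component_def("water", list(
      peak_spec(1640, 110, 1.0, 0.7, shifts = TRUE),
      peak_spec(790, 160, 0.25, 0.8)),
      shift_coefficient = -25),
    component_def("ethanol", list(
      peak_spec(884, 18, 1.0, 0.4),
      peak_spec(1052, 24, 0.45, 0.5),
      peak_spec(1096, 24, 0.40, 0.5),
      peak_spec(1276, 30, 0.22, 0.5),
      peak_spec(1454, 34, 0.50, 0.6))),
    component_def("methanol", list(
      peak_spec(1034, 16, 1.0, 0.45),
      peak_spec(1453, 36, 0.35, 0.6))),
    component_def("glycerol", list(
      peak_spec(850, 22, 1.0, 0.5),
      peak_spec(976, 26, 0.45, 0.5),
      peak_spec(1060, 28, 0.55, 0.5),
      peak_spec(1130, 28, 0.42, 0.5),
      peak_spec(1465, 40, 0.60, 0.6))),
    component_def("formaldehyde", list(
      peak_spec(908, 14, 1.0, 0.45),
      peak_spec(1241, 26, 0.40, 0.5),
      peak_spec(1492, 24, 0.55, 0.5))),
    component_def("phenoxetol", list(
      peak_spec(1000, 12, 1.0, 0.35),
      peak_spec(1250, 28, 0.40, 0.5),
      peak_spec(1600, 20, 0.50, 0.45),
      peak_spec(770, 18, 0.30, 0.5))),
    component_def("picric_acid", list(
      peak_spec(1340, 22, 1.0, 0.45),
      peak_spec(820, 16, 0.40, 0.5),
      peak_spec(1565, 20, 0.35, 0.5),
      peak_spec(1610, 18, 0.30, 0.5))),
    component_def("ethylene_glycol", list(
      peak_spec(865, 20, 1.0, 0.5),
      peak_spec(1062, 26, 0.50, 0.5),
      peak_spec(1090, 26, 0.45, 0.5),
      peak_spec(1270, 30, 0.30, 0.5),
      peak_spec(1460, 38, 0.50, 0.6))),
    component_def("potassium_acetate", list(
      peak_spec(926, 16, 1.0, 0.45),
      peak_spec(1415, 30, 0.50, 0.55))),
    component_def("acetic_acid", list(
      peak_spec(893, 18, 1.0, 0.45),
      peak_spec(1415, 30, 0.45, 0.55),
      peak_spec(1715, 26, 0.30, 0.5))),
    component_def("potassium_nitrate", list(
      peak_spec(1050, 10, 1.0, 0.4))),
    component_def("dowicil", list(
      peak_spec(1145, 18, 1.0, 0.45),
      peak_spec(1380, 24, 0.50, 0.5),
      peak_spec(1555, 22, 0.40, 0.5),
      peak_spec(790, 18, 0.30, 0.5)))
  )
  names(lib) <- vapply(lib, function(d) d$name, "")
  lib
}

#' Define a fluid recipe
#'
#' A labelled mixture of library components by volume fraction. Fractions may
#' be given as fixed numbers or as `c(lo, hi)` ranges; ranges are realized per
#' replicate by uniform jitter (see [generate_calibration_set()]) and must sum
#' to 1 at their midpoints.
#'
#' @param label Class label (e.g. `"C5"`) or scenario name.
#' @param components Named list: component name -> fraction or `c(lo, hi)`.
#' @param excipient Main excipient group (`"ethanol"`, `"formaldehyde"`,
#'   `"glycerol"`, ...), used by the replicate-ambiguity rules.
#' @return A list of class `fluid_recipe`.
#' @export
fluid_recipe <- function(label, components, excipient = NA_character_) {
  mids <- vapply(components, mean, numeric(1))
  if (any(mids < 0) || any(vapply(components, max, numeric(1)) > 1)) {
    stop("fluid_recipe: fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(mids) - 1) > 1e-9) {
    stop(sprintf("fluid_recipe %s: midpoint fractions sum to %.6f, not 1",
                 label, sum(mids)), call. = FALSE)
  }
  structure(list(label = label, components = components, excipient = excipient),
            class = "fluid_recipe")
}

# Realize a recipe's fractions: ranges at their midpoint (jitter = 0) or
# uniformly within the range (jitter = 1), renormalized to sum 1.
realize_fractions <- function(recipe, jitter = 0) {
  fr <- vapply(recipe$components, function(f) {
    if (length(f) == 2L && jitter > 0) stats::runif(1, min(f), max(f)) else mean(f)
  }, numeric(1))
  fr / sum(fr)
}

#' Mix a fluid recipe into a spectrum
#'
#' Fraction-weighted sum of rendered components. Before summation, each
#' component's designated broad bands are shifted by
#' `shift_coefficient * (1 - own fraction)`, i.e. by its co-solute fraction.
#'
#' @param recipe A [fluid_recipe()]; ranges are taken at their midpoint
#'   unless `fractions` is supplied.
#' @param library Component library, as from [default_component_library()].
#' @param axis Wavenumber axis.
#' @param fractions Optional realized fractions (named or in recipe order)
#'   overriding the recipe midpoints.
#' @return A non-negative `sors_spectrum`.
#' @export
mix_fluid <- function(recipe, library = default_component_library(), axis,
                      fractions = NULL) {
  nm <- names(recipe$components)
  missing <- setdiff(nm, names(library))
  if (length(missing)) {
    stop("mix_fluid: unknown component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fr <- if (is.null(fractions)) realize_fractions(recipe, 0) else fractions
  y <- rep(0, length(axis))
  for (i in seq_along(nm)) {
    def <- library[[nm[i]]]
    shift <- def$shift_coefficient * (1 - fr[i])
    y <- y + fr[i] * render_component(def, axis, center_shift = shift)$intensity
  }
  spectrum(axis, y, list(recipe = recipe$label, channel = "reference"))
}

#' Calibration-fluid recipe registry
#'
#' The thirteen printed mock-fluid classes C1-C13 (glycerol, ethanol,
#' ethanol + methanol/formaldehyde, and formaldehyde series), plus
#' artifact-defined stand-in recipes for the named historical formulations
#' C14-C20 (ethanol 96%, formaldehyde 10%, Steedman's, Kaiserling III,
#' Bouin's aqueous/alcoholic, phenoxetol) whose full compositions are not
#' tabulated anywhere; the stand-ins are synthetic constructions for the
#' simulator, not documented recipes.
#'
#' @param classes Character vector of labels to return (default C1-C13).
#' @return Named list of [fluid_recipe()] objects.
#' @export
calibration_recipes <- function(classes = paste0("C", 1:13)) {
  r <- list(
    fluid_recipe("C1", list(glycerol = 0.05, water = 0.95), "glycerol"),
    fluid_recipe("C2", list(glycerol = 0.35, water = 0.65), "glycerol"),
    fluid_recipe("C3", list(glycerol = 0.65, water = 0.35), "glycerol"),
    fluid_recipe("C4", list(ethanol = c(0.50, 0.60), water = c(0.50, 0.40)), "ethanol"),
    fluid_recipe("C5", list(ethanol = c(0.70, 0.80), water = c(0.30, 0.20)), "ethanol"),
    fluid_recipe("C6", list(ethanol = 0.95, methanol = 0.03, water = 0.02), "ethanol"),
    fluid_recipe("C7", list(ethanol = 0.70, methanol = 0.05, water = 0.25), "ethanol"),
    fluid_recipe("C8", list(ethanol = 0.70, methanol = 0.10, water = 0.20), "ethanol"),
    fluid_recipe("C9", list(ethanol = 0.50, formaldehyde = 0.02, water = 0.48), "ethanol"),
    fluid_recipe("C10", list(ethanol = 0.70, formaldehyde = 0.01, water = 0.29), "ethanol"),
    fluid_recipe("C11", list(formaldehyde = c(0.04, 0.05), water = c(0.96, 0.95)), "formaldehyde"),
    fluid_recipe("C12", list(formaldehyde = 0.04, methanol = c(0.015, 0.02),
                             water = c(0.945, 0.94)), "formaldehyde"),
    fluid_recipe("C13", list(formaldehyde = 0.01, water = 0.99), "formaldehyde"),
    # ---- synthetic stand-ins for named historical formulations ----
    fluid_recipe("C14", list(ethanol = 0.96, water = 0.04), "ethanol"),
    fluid_recipe("C15", list(formaldehyde = 0.10, water = 0.90), "formaldehyde"),
    fluid_recipe("C16", list(phenoxetol = 0.01, formaldehyde = 0.01,
                             water = 0.98), "phenoxetol"),           # Steedman's-like
    fluid_recipe("C17", list(formaldehyde = 0.02, potassium_nitrate = 0.01,
                             potassium_acetate = 0.01, glycerol = 0.30,
                             water = 0.66), "glycerol"),             # Kaiserling III-like
    fluid_recipe("C18", list(formaldehyde = 0.10, picric_acid = 0.01,
                             acetic_acid = 0.05, water = 0.84), "formaldehyde"), # Bouin's aqueous-like
    fluid_recipe("C19", list(ethanol = 0.70, formaldehyde = 0.05,
                             picric_acid = 0.03, acetic_acid = 0.02,
                             water = 0.20), "ethanol"),              # Bouin's alcoholic-like
    fluid_recipe("C20", list(phenoxetol = 0.02, water = 0.98), "phenoxetol")
  )
  names(r) <- vapply(r, function(x) x$label, "")
  missing <- setdiff(classes, names(r))
  if (length(missing)) {
    stop("calibration_recipes: unknown class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r[classes]
}

#' Container-material definitions
#'
#' Glasses are modelled as broad fluorescence envelopes (smooth wide humps at
#' material-specific positions under near-infrared excitation); polymers and
#' acrylics as rich sharp Raman band sets. `intensity_scale` sets the
#' container signal relative to a unit-height fluid spectrum.
#'
#' @param materials Which materials to return; default all six.
#' @return Named list of container definitions (class `container_def`).
#' @export
container_library <- function(materials = c("borosilicate", "soda_lime",
                                            "lead_glass", "pmma", "ldpe", "pp")) {
  cdef <- function(material, peaks, intensity_scale, kind) {
    structure(list(name = material, material = material, peaks = peaks,
                   intensity_scale = intensity_scale, kind = kind),
              class = c("container_def", "component_def"))
  }
  lib <- list(
    cdef("borosilicate", list(
      peak_spec(1150, 420, 1.0, 0.9),
      peak_spec(1500, 320, 0.55, 0.9)), 3.0, "glass"),
    cdef("soda_lime", list(
      peak_spec(900, 380, 1.0, 0.9),
      peak_spec(1380, 300, 0.45, 0.9)), 3.0, "glass"),
    cdef("lead_glass", list(
      peak_spec(1560, 440, 1.0, 0.9),
      peak_spec(820, 200, 0.5, 0.9)), 3.0, "glass"),
    cdef("pmma", list(
      peak_spec(812, 16, 1.0, 0.45),
      peak_spec(964, 20, 0.40, 0.5),
      peak_spec(1240, 26, 0.30, 0.5),
      peak_spec(1450, 28, 0.60, 0.55),
      peak_spec(1728, 22, 0.80, 0.5)), 1.5, "polymer"),
    cdef("ldpe", list(
      peak_spec(1062, 16, 0.60, 0.45),
      peak_spec(1130, 16, 0.70, 0.45),
      peak_spec(1296, 18, 1.0, 0.45),
      peak_spec(1440, 26, 0.80, 0.55)), 1.5, "polymer"),
    cdef("pp", list(
      peak_spec(809, 14, 1.0, 0.45),
      peak_spec(841, 14, 0.90, 0.45),
      peak_spec(973, 18, 0.50, 0.5),
      peak_spec(1152, 18, 0.40, 0.5),
      peak_spec(1330, 20, 0.40, 0.5),
      peak_spec(1458, 26, 0.70, 0.55)), 1.5, "polymer")
  )
  names(lib) <- vapply(lib, function(d) d$name, "")
  missing <- setdiff(materials, names(lib))
  if (length(missing)) {
    stop("container_library: unknown material(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lib[materials]
}

#' Default simulation axis
#'
#' 600-1900 cm^-1 in 2 cm^-1 steps: wide enough that truncation to the
#' 750-1800 cm^-1 analysis window never touches an edge.
#'
#' @return Numeric wavenumber axis.
#' @export
default_axis <- function() seq(600, 1900, by = 2)
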