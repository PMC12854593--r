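test_that("rendered components are analytic pseudo-Voigt sums, unit maximum", {
  ax <- seq(800, 1200, 0.5)
  def <- component_def("gauss", list(peak_spec(1000, 20, 1, shape_mix = 1)))
  r <- render_component(def, ax)
  sigma <- 20 / (2 * sqrt(2 * log(2)))
  expect_lt(max(abs(r$intensity - exp(-(ax - 1000)^2 / (2 * sigma^2)))), 1e-9)
  # two identical peaks at one centre == one peak of doubled amplitude
  two <- component_def("d2", list(peak_spec(1000, 20, 1), peak_spec(1000, 20, 1)))
  one <- component_def("d1", list(peak_spec(1000, 20, 2)))
  expect_equal(render_component(two, ax)$intensity,
               render_component(one, ax)$intensity)
  expect_warning(render_component(def, seq(990, 1010, 1)), "3 FWHM")
})

test_that("library marker bands sit at their anchored positions", {
  ax <- default_axis()
  lib <- default_component_library()
  met <- render_component(lib$methanol, ax)
  expect_equal(ax[which.max(met$intensity)], 1034)
  ka <- render_component(lib$potassium_acetate, ax)
  expect_equal(ax[which.max(ka$intensity)], 926)
  for (d in lib) {
    expect_true(all(render_component(d, ax)$intensity >= 0))
  }
  for (d in container_library()) {
    expect_true(all(render_component(d, ax)$intensity >= 0))
  }
})

test_that("fluid mixing is fraction-weighted with concentration band shifts", {
  ax <- default_axis()
  lib <- default_component_library()
  pure <- mix_fluid(fluid_recipe("w", list(water = 1)), lib, ax)
  expect_equal(pure$intensity, render_component(lib$water, ax)$intensity)
  expect_error(mix_fluid(fluid_recipe("x", list(unobtainium = 1)), lib, ax),
               "unknown component")
  # glycerol marker (850 cm-1) heights in C3 (65%) vs C1 (5%): ratio ~ 13
  water_at <- function(frac) {
    frac * render_component(lib$water, ax,
                            center_shift = lib$water$shift_coefficient *
                              (1 - frac))$intensity
  }
  i850 <- which(ax == 850)
  h1 <- mix_fluid(calibration_recipes()$C1, lib, ax)$intensity[i850] -
    water_at(0.95)[i850]
  h3 <- mix_fluid(calibration_recipes()$C3, lib, ax)$intensity[i850] -
    water_at(0.35)[i850]
  expect_lt(abs(h3 / h1 - 13) / 13, 0.10)
  # designated OH band shifts by shift_coefficient x co-solute difference
  mix70 <- mix_fluid(fluid_recipe("e70", list(ethanol = 0.7, water = 0.3)),
                     lib, ax)
  mix95 <- mix_fluid(fluid_recipe("e95", list(ethanol = 0.95, water = 0.05)),
                     lib, ax)
  apex <- function(s) {
    w <- s$wavenumber >= 1500 & s$wavenumber <= 1750
    x <- s$wavenumber[w]; y <- s$intensity[w]
    p <- which.max(y)
    d <- y[p - 1] - 2 * y[p] + y[p + 1]
    x[p] + 0.5 * (y[p - 1] - y[p + 1]) / d * (x[p + 1] - x[p])
  }
  # co-solute fraction of water rises from 0.70 to 0.95
  shift <- apex(mix95) - apex(mix70)
  expected <- lib$water$shift_coefficient * 0.25
  expect_equal(shift, expected, tolerance = 1.5)
})

test_that("simulated channels follow the two-layer mixing model exactly", {
  ax <- default_axis()
  rec <- calibration_recipes()$C6          # fixed composition: deterministic
  cont <- container_library()[["borosilicate"]]
  m <- simulate_measurement(rec, cont,
                            mixing_model(1, 0, 0.3, 0.7),
                            noise_off(), ax, seed = 1)
  expect_equal(m$zero$intensity, m$ground_truth$container_clean)
  m2 <- simulate_measurement(rec, cont,
                             mixing_model(0.8, 1e-9, 1e-12, 1),
                             noise_off(), ax, seed = 1)
  expect_lt(max(abs(m2$offset$intensity - m2$ground_truth$fluid_clean)), 1e-8)
  expect_error(mixing_model(0.8, 0.2, 0.8, 0.2), "subsurface-enriched")
})

test_that("simulation is seed-deterministic with independent noise draws", {
  a <- sim_default("C5", "soda_lime", noise_model(), seed = 42)
  b <- sim_default("C5", "soda_lime", noise_model(), seed = 42)
  c2 <- sim_default("C5", "soda_lime", noise_model(), seed = 43)
  expect_identical(a$zero$intensity, b$zero$intensity)
  expect_identical(a$offset$intensity, b$offset$intensity)
  expect_false(identical(a$zero$intensity, c2$zero$intensity))
})

test_that("noisy channels are unbiased around the clean mixture", {
  ax <- seq(800, 1000, 4)
  rec <- fluid_recipe("w", list(water = 1))
  cont <- container_library()[["soda_lime"]]
  quiet <- noise_model(drift_sd = 0, fluid_fluorescence_scale = 0)
  draws <- withr::with_seed(5, {
    vapply(1:200, function(i) {
      simulate_measurement(rec, cont, noise = quiet,
                           axis = ax, seed = NULL)$zero$intensity
    }, numeric(length(ax)))
  })
  clean <- simulate_measurement(rec, cont, noise = noise_off(),
                                axis = ax, seed = 1)$zero$intensity
  se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - clean) < 3.5 * pmax(se, 1e-12)))
})

test_that("the offset channel is always subsurface-enriched", {
  m <- sim_default("C2", "lead_glass", noise_off(), seed = 2)
  energy <- function(ch, part) sum((ch * part)^2)
  tr <- m$ground_truth
  r_off <- sum(m$offset$intensity * tr$fluid_clean) /
    sum(m$offset$intensity * tr$container_clean)
  r_zero <- sum(m$zero$intensity * tr$fluid_clean) /
    sum(m$zero$intensity * tr$container_clean)
  expect_gt(r_off, r_zero)
  # invariant holds for randomly drawn valid mixing models
  withr::with_seed(8, {
    for (i in 1:10) {
      az <- runif(1, 0.5, 0.95); ao <- runif(1, 0.1, 0.45)
      mm <- mixing_model(az, 1 - az, ao, 1 - ao)
      expect_gt(mm$offset_fluid / mm$offset_container,
                mm$zero_fluid / mm$zero_container)
    }
  })
})

test_that("calibration sets have the documented shape and determinism", {
  cs <- generate_calibration_set(calibration_recipes(), 6, seed = 1)
  expect_length(cs$measurements, 13 * 6)
  expect_equal(as.vector(table(cs$labels)), rep(6, 13))
  cs2 <- generate_calibration_set(calibration_recipes(), 6, seed = 1)
  expect_identical(cs$measurements[[5]]$zero$intensity,
                   cs2$measurements[[5]]$zero$intensity)
  # fixed-composition class, noise off: replicates are identical
  quiet <- generate_calibration_set(calibration_recipes(c("C6", "C13")), 2,
                                    noise = noise_off(), seed = 3)
  expect_identical(quiet$measurements[[1]]$offset$intensity,
                   quiet$measurements[[2]]$offset$intensity)
  dup <- calibration_recipes(c("C1", "C2"))
  names(dup) <- NULL
  dup[[2]] <- dup[[1]]
  expect_error(generate_calibration_set(dup, 2, seed = 1), "duplicate")
})

test_that("cohorts carry one truth row per sample and rewrite byte-identically", {
  scen <- default_cohort_scenarios()
  expect_length(scen, 46)
  cohort <- generate_cohort(scen, seed = 4)
  expect_length(cohort$records, 46)
  expect_equal(nrow(cohort$truth), 46)
  expect_equal(sum(cohort$truth$true_fluid == "OUT_OF_SET"), 6)
  expect_setequal(unique(cohort$truth$true_container),
                  names(container_library()))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(scen[1:4], seed = 9), d1)
  write_cohort(generate_cohort(scen[1:4], seed = 9), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
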