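test_that("scaling factor recovers proportionality and windowed orthogonality", {
  ax <- toy_axis()
  z <- spectrum(ax, 1 + pseudo_voigt(ax, 1200, 40))
  o <- spectrum(ax, 2 * z$intensity)
  expect_equal(estimate_scaling_factor(z, o, direction = "forward"), 2,
               tolerance = 1e-3)
  # orthogonal signals within the window: no shared component, SF = 0
  cfg <- preprocess_config(sf_window = c(1100, 1300))
  # pure Gaussians: the zero channel is numerically zero inside the window
  z2 <- spectrum(ax, pseudo_voigt(ax, 800, 30, shape_mix = 1))
  o2 <- spectrum(ax, pseudo_voigt(ax, 1200, 30, shape_mix = 1))
  expect_equal(estimate_scaling_factor(z2, o2, cfg, "forward"), 0)
  zz <- spectrum(ax, rep(0, length(ax)))
  expect_error(estimate_scaling_factor(zz, o, direction = "forward"),
               "identically zero")
})

test_that("forward SF matches the brute-force negativity-penalty oracle", {
  # known two-layer mixing: container 0.8 in zero, 0.3 in offset
  m <- sim_default("C5", "soda_lime", noise_off(), seed = 3)
  z <- truncate_spectrum(m$zero); o <- truncate_spectrum(m$offset)
  sf <- estimate_scaling_factor(z, o, direction = "forward")
  nulling <- 0.3 / 0.8
  expect_lt(abs(sf - nulling) / nulling, 0.05)
  # independent oracle: exhaustive fine-grid scan of the penalty with the
  # same largest-SF-within-tolerance rule
  grid <- seq(0, 3, by = 0.001)
  pen <- vapply(grid, function(s) {
    sum(pmin(o$intensity - s * z$intensity, 0)^2)
  }, numeric(1))
  thr <- min(pen) + 1e-6 * (max(pen) - min(pen))
  oracle <- grid[max(which(pen <= thr))]
  expect_equal(sf, oracle, tolerance = 1e-6)
})

test_that("scaled subtractions behave linearly and cancel exactly", {
  ax <- toy_axis()
  z <- toy_spectrum(seed = 4); o <- toy_spectrum(seed = 5)
  expect_equal(sors_subtract(z, o, 0)$intensity, o$intensity)
  expect_equal(reverse_sors(z, o, 0)$intensity, z$intensity)
  expect_true(all(abs(sors_subtract(z, z, 1)$intensity) < 1e-12))
  expect_true(all(abs(reverse_sors(z, z, 1)$intensity) < 1e-12))
  # linearity in both arguments
  a <- 0.7
  lhs <- sors_subtract(z, o, a)$intensity
  expect_equal(lhs, o$intensity - a * z$intensity)
  s2 <- spectrum(ax, 2 * o$intensity)
  expect_equal(sors_subtract(z, s2, a)$intensity,
               2 * o$intensity - a * z$intensity)
})

test_that("oracle-SF subtraction isolates each layer on noiseless pairs", {
  for (cont in c("soda_lime", "pmma")) {
    m <- sim_default("C8", cont, noise_off(), seed = 5)
    z <- truncate_spectrum(m$zero); o <- truncate_spectrum(m$offset)
    # oracle scaling factors from the known mixing weights
    mix <- m$ground_truth$mixing
    fl <- sors_subtract(z, o, mix$offset_container / mix$zero_container)
    fl <- snv(baseline_correct(fl))
    expect_gt(cosine(fl$intensity, oracle_fluid(m)$intensity), 0.999)
    cont_sp <- reverse_sors(z, o, mix$zero_fluid / mix$offset_fluid)
    expect_gt(cosine(cont_sp$intensity, oracle_container(m)$intensity), 0.999)
  }
})

test_that("baseline correction annihilates polynomials and preserves peaks", {
  ax <- toy_axis()
  u <- (ax - mean(ax)) / 500
  poly5 <- 3 + u - 2 * u^2 + u^3 + 0.5 * u^4 - u^5
  s <- spectrum(ax, poly5)
  out <- baseline_correct(s, 5, 20)
  expect_lt(max(abs(out$intensity)), 1e-6 * diff(range(poly5)))
  # polynomial + one narrow positive peak: peak kept, background gone
  peak <- pseudo_voigt(ax, 1300, 16, 1, 0.5)
  out2 <- baseline_correct(spectrum(ax, poly5 + peak), 5, 20)
  expect_lt(abs(max(out2$intensity) - 1), 0.05)
  off_peak <- abs(ax - 1300) > 160
  expect_lt(max(abs(out2$intensity[off_peak])), 0.02)
  # flat zero input stays zero; never grows the maximum
  z0 <- baseline_correct(spectrum(ax, rep(0, length(ax))), 5, 5)
  expect_true(all(abs(z0$intensity) < 1e-12))
  expect_lte(max(out2$intensity), max(poly5 + peak) + 1e-9)
  expect_error(baseline_correct(spectrum(1:4, 1:4), 5), "order 5")
})

test_that("SNV standardizes every spectrum and is affine invariant", {
  s <- toy_spectrum(seed = 8)
  n <- snv(s)
  expect_lt(abs(mean(n$intensity)), 1e-12)
  expect_lt(abs(stats::sd(n$intensity) - 1), 1e-12)
  aff <- spectrum(s$wavenumber, 3.7 * s$intensity + 11)
  expect_equal(snv(aff)$intensity, n$intensity, tolerance = 1e-10)
  flat <- spectrum(1:10, rep(5, 10))
  expect_true(all(snv(flat)$intensity == 0))
})

test_that("process_measurement recovers both layers from noiseless pairs", {
  m <- sim_default("C7", "soda_lime", noise_off(), seed = 9)
  pp <- process_measurement(m)
  expect_false(pp$degenerate)
  expect_gt(cosine(pp$fluid_spectrum$intensity, oracle_fluid(m)$intensity),
            0.999)
  # the container layer is recovered to high (not perfect) fidelity: the
  # fluid-nulling ratio is only weakly identifiable under a dominant
  # container, so the reverse branch tolerates a small fluid residue
  expect_gt(cosine(pp$container_spectrum$intensity,
                   oracle_container(m)$intensity), 0.99)
  expect_lt(pp$container_sharpness, 0.05)   # glass: smooth container
  mp <- process_measurement(sim_default("C7", "pp", noise_off(), seed = 9))
  expect_gt(mp$container_sharpness, 0.05)   # polymer: Raman-sharp container
  expect_equal(mp$container_match, "pp")
})

test_that("a measurement with no zero/offset contrast is flagged degenerate", {
  m <- sim_default("C5", "soda_lime", noise_off(), seed = 10)
  m2 <- sors_measurement(m$sample_id, m$replicate_id, m$zero, m$zero,
                         ground_truth = m$ground_truth)
  pp <- process_measurement(m2)
  expect_true(pp$degenerate)
})
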