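test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(1, 1), "at least 2")
  expect_error(spectrum(c(1, 2, 2), c(1, 2, 3)), "monotone")
  expect_error(spectrum(c(1, 2, NA), c(1, 2, 3)), "non-finite")
  expect_error(spectrum(1:3, c(1, 2)), "intensity has")
  expect_error(spectrum(1:3, c(1, -1, 2), list(channel = "zero")), "negative")
  # descending axis is reordered together with intensities
  s <- spectrum(c(30, 20, 10), c(3, 2, 1))
  expect_equal(s$wavenumber, c(10, 20, 30))
  expect_equal(s$intensity, c(1, 2, 3))
  # processed channels may be negative
  expect_silent(spectrum(1:3, c(1, -1, 2), list(channel = "processed")))
})

test_that("csv2col write/read round-trip preserves spectra and metadata", {
  s <- toy_spectrum()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_lt(max(abs(r$wavenumber - s$wavenumber)), 1e-9)
  expect_lt(max(abs(r$intensity - s$intensity)),
            1e-9 * max(abs(s$intensity)))
  expect_equal(r$meta$sample_id, "T1")
})

test_that("csv2col reader sorts descending files and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sample_id: X", "1200,3", "1100,2", "1000,1"), path)
  r <- read_spectrum(path)
  expect_equal(r$wavenumber, c(1000, 1100, 1200))
  expect_equal(r$intensity, c(1, 2, 3))

  writeLines(c("1000,1,9", "1100,2,9"), path)
  expect_error(read_spectrum(path), "2 columns")
  writeLines(c("1000,1", "abc,2"), path)
  expect_error(read_spectrum(path), "row 2")
  expect_error(read_spectrum(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("JCAMP-DX XYDATA reader recovers a uniform-grid spectrum", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=demo", "##XFACTOR=1", "##YFACTOR=0.5",
               "##XYDATA=(X++(Y..Y))",
               "800 2 4 6", "806 8 10 12", "##END="), path)
  r <- read_spectrum(path, dialect = "jcampdx")
  expect_equal(r$wavenumber, seq(800, 810, by = 2))
  expect_equal(r$intensity, seq(1, 6, by = 1) * 1)
  expect_equal(r$intensity, c(1, 2, 3, 4, 5, 6))
})

test_that("resample interpolates linearly and refuses extrapolation", {
  s <- toy_spectrum()
  expect_equal(resample(s, s$wavenumber)$intensity, s$intensity)
  # linear ramp hits midpoints exactly
  ramp <- spectrum(seq(0, 10, 1), seq(0, 10, 1) * 2)
  mid <- resample(ramp, seq(0.5, 9.5, 1))
  expect_equal(mid$intensity, seq(0.5, 9.5, 1) * 2)
  expect_error(resample(s, c(600, 700)), "outside source span")
  # pseudo-Voigt on 1 cm-1 grid resampled to 0.5 cm-1: error below 1% of peak
  coarse_ax <- seq(900, 1100, 1)
  fine_ax <- seq(900, 1100, 0.5)
  pv <- function(x) pseudo_voigt(x, 1000, 12, 1, 0.3)
  est <- resample(spectrum(coarse_ax, pv(coarse_ax)), fine_ax)
  expect_lt(max(abs(est$intensity - pv(fine_ax))), 0.01)
})

test_that("truncate keeps the closed analysis window and is idempotent", {
  wide <- spectrum(seq(200, 3200, 1), rep(1, 3001))
  t1 <- truncate_spectrum(wide)
  expect_equal(length(t1), 1051)  # integers in [750, 1800]
  expect_equal(range(t1$wavenumber), c(750, 1800))
  expect_equal(truncate_spectrum(t1), t1)
  inside <- spectrum(seq(800, 1700, 2), rep(1, 451))
  expect_equal(truncate_spectrum(inside)$wavenumber, inside$wavenumber)
  expect_error(truncate_spectrum(wide, 5000, 6000), "overlap")
  expect_error(truncate_spectrum(wide, 1800, 750), "lo < hi")
})

test_that("average_replicates is a permutation-invariant pointwise mean", {
  a <- toy_spectrum(seed = 1); b <- toy_spectrum(seed = 2)
  c3 <- toy_spectrum(seed = 3)
  expect_equal(average_replicates(list(a))$intensity, a$intensity)
  expect_equal(average_replicates(list(a, a))$intensity, a$intensity)
  two <- spectrum(1:5, rep(1, 5)); six <- spectrum(1:5, rep(3, 5))
  expect_equal(average_replicates(list(two, six))$intensity, rep(2, 5))
  m1 <- average_replicates(list(a, b, c3))$intensity
  m2 <- average_replicates(list(c3, a, b))$intensity
  expect_equal(m1, m2)
  short <- spectrum(1:4, 1:4)
  expect_error(average_replicates(list(a, short)), "common axis")
})

test_that("manifests round-trip through write_cohort and skip missing files", {
  scen <- default_cohort_scenarios()[1:3]
  cohort <- generate_cohort(scen, seed = 11)
  dir <- withr::local_tempdir()
  mp <- write_cohort(cohort, dir)
  recs <- read_manifest(mp)
  expect_length(recs, 3)
  expect_equal(length(recs[[1]]$measurements), 2)
  # removing one offset file drops that replicate with a warning only
  victim <- list.files(dir, pattern = "A01_rep01_offset", full.names = TRUE)
  unlink(victim)
  expect_warning(recs2 <- read_manifest(mp), "A01/rep01")
  expect_length(recs2, 3)
  expect_equal(length(recs2[["A01"]]$measurements), 1)
  expect_equal(length(recs2[["A02"]]$measurements), 2)
})
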