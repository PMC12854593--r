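# Shared fixtures: small deterministic spectra and simulator shortcuts.

toy_axis <- function() seq(700, 1900, by = 2)

toy_spectrum <- function(axis = toy_axis(), seed = 1) {
  withr::with_seed(seed, {
    y <- 0.2 + pseudo_voigt(axis, 1000, 30, 1, 0.5) +
      0.5 * pseudo_voigt(axis, 1500, 50, 1, 0.5) +
      abs(rnorm(length(axis), 0, 0.01))
  })
  spectrum(axis, y, list(sample_id = "T1", replicate_id = "r1"))
}

# One simulated measurement under default study conditions.
sim_default <- function(class = "C5", container = "soda_lime",
                        noise = noise_off(), seed = 7, mixing = mixing_model(),
                        sample_id = class, replicate_id = "r1") {
  simulate_measurement(calibration_recipes()[[class]],
                       container_library()[[container]],
                       mixing = mixing, noise = noise, seed = seed,
                       sample_id = sample_id, replicate_id = replicate_id)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Oracle fluid reference: what the pipeline should recover for a measurement.
oracle_fluid <- function(m, config = preprocess_config()) {
  s <- truncate_spectrum(spectrum(m$zero$wavenumber,
                                  pmax(m$ground_truth$fluid_clean, 0),
                                  list(channel = "processed")),
                         config$truncate_lo, config$truncate_hi)
  snv(baseline_correct(s, config$baseline_order, config$baseline_iterations))
}

oracle_container <- function(m, config = preprocess_config()) {
  truncate_spectrum(spectrum(m$zero$wavenumber, m$ground_truth$container_clean,
                             list(channel = "processed")),
                    config$truncate_lo, config$truncate_hi)
}
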