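# Small fixtures built in code.

# A compact simulation config for fast tests: coarse axis covering the
# modelling window, few eggs.
small_config <- function(seed = 1, n_eggs_per_class = 8, rotations_per_egg = 2, ...) {
  sim_config(
    axis = seq(450, 720, length.out = 300),
    n_eggs_per_class = n_eggs_per_class, rotations_per_egg = rotations_per_egg,
    seed = seed, ...
  )
}

# Random spectra tibble with labels, for model-level tests.
random_spectra <- function(n = 20, p = 10, seed = 1, classes = 0:2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  as_spectra(X, axis = seq(500, 500 + p - 1), class = rep_len(classes, n))
}

# Calibrated, range-restricted transmittance set from a small simulation.
small_transmittance <- function(seed = 1, lo = 500, hi = 680, ...) {
  ds <- simulate_dataset(small_config(seed = seed, ...))
  restrict_range(calibrate(ds$spectra, ds$references), lo, hi)
}

# Fabricate a selection_result for pooling tests.
fake_selection <- function(method, wavelengths) {
  eggspec:::selection_result(method, wavelengths, seq_along(wavelengths),
                             tibble::tibble())
}
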