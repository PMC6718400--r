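# Shared fixture builders: everything is generated in code at test time.

fixture_interferents <- function(axis) {
  list(water = water_profile(axis), fluorescence = fluorescence_profile(axis))
}

# EMSC basis whose reference is estimated from a clean control population
fixture_basis <- function(axis, seed = 99L) {
  interf <- fixture_interferents(axis)
  ctrl <- simulate_population(
    population_spec(n_cells = 200, empty_rate = 0, spike_rate = 0, seed = seed),
    component_library(axis), axis)$spectra
  ref <- estimate_pure_cell(remove_spikes(ctrl)$spectra, interf)
  emsc_basis(ref, axis, interferents = interf)
}

# two separable point clouds in score space with labels
fixture_clouds <- function(n_per = 20, delta = 6, sigma = 0.5, seed = 1L) {
  set.seed(seed)
  scores <- rbind(matrix(rnorm(2 * n_per, 0, sigma), ncol = 2) +
                    matrix(c(delta / 2, 0), n_per, 2, byrow = TRUE),
                  matrix(rnorm(2 * n_per, 0, sigma), ncol = 2) +
                    matrix(c(-delta / 2, 0), n_per, 2, byrow = TRUE))
  list(scores = scores, labels = rep(c("viable", "non_viable"), each = n_per))
}
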