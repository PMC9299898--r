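# Shared fixtures: small grids and quick fit settings keep unit tests fast;
# the acceptance tests use the full default grids.

quick_grid <- function() seq(185, 260, by = 2.5)   # 31 wavelengths

quick_temps <- function() seq(283.15, 353.15, by = 5)  # 15 temperatures

two_state_model <- function() {
  thermo_model(c("disordered", "beta_turn"), c(0, 5.4), c(0, 18))
}

three_state_model <- function() {
  thermo_model(c("disordered", "beta_turn", "assembly"),
               c(0, 9.9, 89.1), c(0, 33, 270))
}

# noiseless bilinear series from explicit spectra and populations
exact_series <- function(model, grid = quick_grid(), temps = quick_temps()) {
  basis <- make_basis_spectra(default_band_models()[model$species], grid)
  S <- vapply(basis$cd, function(b) b$value, numeric(length(grid)))
  A <- vapply(basis$absorbance, function(b) b$value, numeric(length(grid)))
  P <- population_matrix(model, temps)
  spectral_series(grid, temps, S %*% t(P), A %*% t(P))
}

quick_fit <- function(series, n_species, ...) {
  fit_global(series, n_species = n_species, n_starts = 8, seed = 42, ...)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-12)), tol)
}
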