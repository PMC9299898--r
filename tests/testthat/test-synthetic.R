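# Synthetic-data generator: band models, series synthesis, distortion.

test_that("default band models carry the canonical CD signatures", {
  bm <- default_band_models()
  basis <- make_basis_spectra(bm, default_grid())$cd
  at <- function(b, x) b$value[which.min(abs(b$wavelength_nm - x))]
  expect_lt(at(basis$disordered, 197), 0)
  expect_gt(at(basis$beta_turn, 195), 0)
  expect_lt(at(basis$beta_turn, 222), 0)
  expect_lte(at(basis$assembly, 200), 0)
  expect_lte(at(basis$assembly, 225), 0)
})

test_that("disordered and beta-turn spectra share an isodichroic point at 213 nm", {
  grid <- default_grid()   # contains 213 exactly
  basis <- make_basis_spectra(default_band_models(), grid)$cd
  i213 <- which(grid == 213)
  expect_equal(basis$disordered$value[i213], basis$beta_turn$value[i213],
               tolerance = 1e-12)
  # consequence: every two-species mixture passes through that point
  series <- exact_series(two_state_model(), grid = grid,
                         temps = quick_temps())
  cd213 <- series_matrix(series)[i213, ]
  expect_lt(diff(range(cd213)), 1e-12)
})

test_that("band evaluation is Gaussian: peak value, additivity, area", {
  grid <- seq(185, 260, 0.1)
  one <- list(label = "x",
              cd_bands = tibble::tibble(center = 220, sigma = 6, amplitude = -3),
              abs_bands = tibble::tibble(center = 200, sigma = 8, amplitude = 1))
  b <- make_basis_spectra(list(x = one), grid)
  expect_equal(min(b$cd[[1]]$value), -3, tolerance = 1e-6)
  expect_equal(b$cd[[1]]$value[grid == 220], -3)
  # two identical bands double the spectrum
  two <- one
  two$cd_bands <- dplyr::bind_rows(one$cd_bands, one$cd_bands)
  b2 <- make_basis_spectra(list(x = two), grid)
  expect_equal(b2$cd[[1]]$value, 2 * b$cd[[1]]$value, tolerance = 1e-12)
  # trapezoid area of the unit absorptivity band ~ sigma * sqrt(2*pi)
  area <- sum(diff(grid) * (b$abs[[1]]$value[-1] + b$abs[[1]]$value[-length(grid)]) / 2)
  expect_equal(area, 8 * sqrt(2 * pi), tolerance = 0.005 * 8 * sqrt(2 * pi))
})

test_that("noiseless generation is the exact bilinear model", {
  spec <- synthetic_preset("vpgvg20", noise_sigma = 0)
  spec$temperatures <- quick_temps()
  series <- generate_series(spec, quick_grid())
  basis <- make_basis_spectra(spec$band_models, quick_grid())$cd
  S <- vapply(basis, function(b) b$value, numeric(length(quick_grid())))
  P <- population_matrix(spec$thermo, quick_temps())
  expect_equal(series_matrix(series), S %*% t(P), tolerance = 1e-12,
               ignore_attr = TRUE)
  # back-fit recovers the generating populations
  B <- back_fit_coefficients(series, S)
  expect_lt(max(abs(B - P)), 1e-8)
  # generating coefficients sum to one by construction
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
})

test_that("generation is deterministic in the seed", {
  mk <- function(seed) {
    spec <- synthetic_preset("vpgvg40", noise_sigma = 0.02, seed = seed)
    spec$temperatures <- quick_temps()
    series_matrix(generate_series(spec, quick_grid()))
  }
  expect_identical(mk(7), mk(7))
  expect_false(identical(mk(7), mk(8)))
})

test_that("generator seeding does not disturb the global RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_series(synthetic_preset("vpgvg20",
                                                            noise_sigma = 0.01),
                                           quick_grid()))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("scattering distortion kicks in only above onset and lowers weights", {
  spec <- synthetic_preset("vpgvg40", noise_sigma = 0, scattering = FALSE)
  series <- generate_series(spec, quick_grid())
  distortion <- list(onset_K = 333, rate_per_K = 0.5, scatter_amplitude = 1.5,
                     scatter_mix = c(0.5, 0.5), loss_per_K = 0.008,
                     turbidity_amplitude = 800)
  scb <- scattering_basis_set(default_band_models()[1:2], quick_grid())
  distorted <- apply_scattering_distortion(series, distortion, scb)
  tk <- series_temperatures(series)
  below <- tk <= 333
  expect_equal(series_matrix(distorted)[, below], series_matrix(series)[, below])
  expect_false(isTRUE(all.equal(series_matrix(distorted)[, !below],
                                series_matrix(series)[, !below])))
  # zero-strength distortion is the identity
  null_dist <- distortion
  null_dist$scatter_amplitude <- 0; null_dist$loss_per_K <- 0
  null_dist$turbidity_amplitude <- 0
  expect_equal(series_matrix(apply_scattering_distortion(series, null_dist, scb)),
               series_matrix(series), tolerance = 1e-12)
  # absorbance similarity weights decrease strictly with T above onset
  ab <- series_matrix(distorted, "absorbance")
  ref <- rowMeans(ab[, 1:5])
  w <- scattering_weights(ab, ref)
  above <- which(tk > 333)
  expect_true(all(diff(w[above]) < 0))
  expect_error(apply_scattering_distortion(series,
                                           modifyList(distortion,
                                                      list(onset_K = 500)),
                                           scb),
               "onset")
})

test_that("distorted back-fit coefficients fall below the Boltzmann model", {
  spec <- synthetic_preset("vpgvg40", noise_sigma = 0, scattering = TRUE)
  series <- generate_series(spec, quick_grid())
  basis <- make_basis_spectra(spec$band_models, quick_grid())$cd
  S <- vapply(basis, function(b) b$value, numeric(length(quick_grid())))
  P <- population_matrix(spec$thermo, spec$temperatures)
  B <- back_fit_coefficients(series, S)
  tk <- spec$temperatures
  hot <- tk > spec$scattering$onset_K + 5
  # total recovered material drops below the model's total (=1) when
  # precipitation removes signal
  expect_true(all(rowSums(B)[hot] < 0.995))
  expect_true(all(abs(rowSums(B)[tk < spec$scattering$onset_K] - 1) < 1e-6))
})

test_that("parameter recovery degrades monotonically with noise", {
  noise_levels <- c(0, 0.005, 0.01, 0.02)
  med_err <- vapply(noise_levels, function(ns) {
    errs <- vapply(1:8, function(i) {
      spec <- synthetic_preset("vpgvg20", noise_sigma = ns, seed = 500 + i)
      spec$temperatures <- quick_temps()
      series <- generate_series(spec, quick_grid())
      fit <- suppressWarnings(quick_fit(series, 2))
      td <- tidy(fit)
      max(abs(td$dH_kcal_mol[2] - 5.4) / 5.4, abs(td$dS_cal_mol_K[2] - 18) / 18)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  # non-decreasing within a small tolerance for sampling jitter
  expect_true(all(diff(med_err) > -0.005))
  expect_lt(med_err[1], 1e-4)
})
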