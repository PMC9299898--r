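# MLS global fitting: linear subproblem, residual, weights, prior, back-fit,
# and the full variable-projection fit.

test_that("solve_species_spectra inverts exact bilinear data", {
  set.seed(21)
  S0 <- matrix(rnorm(40), 20, 2)
  P <- population_matrix(two_state_model(), quick_temps())
  cd <- S0 %*% t(P)
  S <- solve_species_spectra(cd, P)
  expect_lt(max(abs(S - S0)), 1e-10)
})

test_that("single-species all-ones coefficients give the row-wise mean", {
  set.seed(22)
  cd <- matrix(rnorm(50), 10, 5)
  S <- solve_species_spectra(cd, matrix(1, 5, 1))
  expect_equal(as.vector(S), rowMeans(cd), tolerance = 1e-12)
})

test_that("weighted solution matches a per-wavelength normal-equations oracle", {
  set.seed(23)
  cd <- matrix(rnorm(20), 5, 4)
  C <- matrix(runif(8), 4, 2)
  w <- c(2, 0.5, 1, 3)
  S <- solve_species_spectra(cd, C, w)
  # brute force: for each wavelength solve (C' W C) s = C' W y
  G <- t(C) %*% diag(w) %*% C
  for (i in 1:5) {
    s_oracle <- solve(G, t(C) %*% diag(w) %*% cd[i, ])
    expect_equal(unname(S[i, ]), as.vector(s_oracle), tolerance = 1e-8)
  }
})

test_that("collinear coefficient columns raise a singularity error", {
  C <- cbind(a = rep(0.5, 6), b = rep(0.5, 6))
  expect_error(solve_species_spectra(matrix(1, 4, 6), C), "collinear.*a.*b")
})

test_that("residual_R is normalized, anchored, and scale invariant", {
  set.seed(24)
  P <- population_matrix(two_state_model(), quick_temps())
  S0 <- matrix(rnorm(30), 15, 2)
  cd <- S0 %*% t(P)
  expect_equal(residual_R(cd, P, S0), 0)
  expect_equal(residual_R(cd, P, S0 * 0), 1)
  noisy_S <- S0 + 0.1
  expect_equal(residual_R(cd * 7, P, noisy_S * 7),
               residual_R(cd, P, noisy_S), tolerance = 1e-12)
  expect_error(residual_R(cd * 0, P, S0), "all-zero")
})

test_that("residual for 5% relative noise falls in the expected band", {
  # Monte-Carlo over generator seeds: R estimates noise-to-signal, so with
  # noise_sigma = 0.05 it must land well within [0.03, 0.15]
  Rs <- vapply(1:40, function(i) {
    spec <- synthetic_preset("vpgvg20", noise_sigma = 0.05, seed = i)
    spec$temperatures <- quick_temps()
    series <- generate_series(spec, quick_grid())
    cd <- series_matrix(series)
    P <- population_matrix(spec$thermo, quick_temps())
    S <- solve_species_spectra(cd, P)
    residual_R(cd, P, S)
  }, numeric(1))
  expect_gt(min(Rs), 0.03)
  expect_lt(max(Rs), 0.15)
})

test_that("scattering weights rank distorted spectra below clean ones", {
  ref <- exp(-(quick_grid() - 200)^2 / 200)
  clean <- cbind(ref, 2 * ref, 0.5 * ref)
  expect_equal(scattering_weights(clean, ref), rep(1, 3))
  # growing long-wavelength scattering tail -> strictly decreasing weight
  tail_shape <- ((quick_grid() - 184) / 40)^2
  distorted <- cbind(ref, ref + 0.5 * tail_shape, ref + 2 * tail_shape)
  w <- scattering_weights(distorted, ref)
  expect_true(all(diff(w) < 0))
  expect_equal(w[1], 1)
  # orthogonal column -> weight 0
  orth <- ref * 0; orth[1] <- 1; orth <- orth - ref * sum(orth * ref) / sum(ref^2)
  expect_equal(unname(scattering_weights(cbind(ref, orth), ref))[2], 0)
})

test_that("prior penalty measures shape mismatch on the cosine scale", {
  ref <- sin(seq(0, pi, length.out = 50))
  S <- cbind(disordered = 3.7 * ref, beta_turn = ref * 0)
  S[, 2] <- cos(seq(0, pi, length.out = 50))  # orthogonal to ref on this grid
  pen <- prior_penalty(S, list(disordered = ref))
  expect_equal(pen, 0, tolerance = 1e-12)
  expect_equal(prior_penalty(S, list(beta_turn = ref)), 1, tolerance = 1e-6)
  # second-order expansion: penalty ~ |d_perp|^2 / (2 |ref|^2)
  set.seed(31)
  delta <- rnorm(50, sd = 1e-3)
  d_perp <- delta - ref * sum(delta * ref) / sum(ref^2)
  S2 <- cbind(disordered = ref + delta)
  expect_equal(prior_penalty(S2, list(disordered = ref)),
               sum(d_perp^2) / (2 * sum(ref^2)), tolerance = 1e-6)
  # species without a reference contribute nothing
  expect_equal(prior_penalty(S, list(assembly = ref)), 0)
})

test_that("back-fit recovers exact mixing coefficients and clips negatives", {
  basis <- make_basis_spectra(default_band_models()[1:2], quick_grid())$cd
  S <- cbind(basis[[1]]$value, basis[[2]]$value)
  y <- 0.3 * S[, 1] + 0.7 * S[, 2]
  B <- back_fit_coefficients(cbind(y), S)
  expect_equal(unname(B[1, ]), c(0.3, 0.7), tolerance = 1e-10)
  Bneg <- back_fit_coefficients(cbind(-0.1 * S[, 1]), S, nonneg = TRUE)
  expect_equal(unname(Bneg[1, 1]), 0)
  Bfree <- back_fit_coefficients(cbind(-0.1 * S[, 1]), S, nonneg = FALSE)
  expect_equal(unname(Bfree[1, ]), c(-0.1, 0), tolerance = 1e-10)
})

test_that("NNLS back-fit agrees with an exhaustive coarse-grid oracle", {
  set.seed(32)
  basis <- make_basis_spectra(default_band_models()[1:2], quick_grid())$cd
  S <- cbind(basis[[1]]$value, basis[[2]]$value)
  step <- 0.02
  grid_pts <- seq(0, 1.2, step)
  for (rep in 1:5) {
    y <- S %*% runif(2, 0.1, 1) + rnorm(nrow(S), sd = 0.15)
    B <- back_fit_coefficients(cbind(y), S)[1, ]
    sse <- function(c1, c2) sum((y - S %*% c(c1, c2))^2)
    o <- expand.grid(c1 = grid_pts, c2 = grid_pts)
    o$sse <- mapply(sse, o$c1, o$c2)
    best <- o[which.min(o$sse), ]
    expect_lt(max(abs(c(best$c1, best$c2) - B)), step)
  }
})

test_that("noiseless two-state global fit recovers planted parameters", {
  series <- exact_series(two_state_model())
  fit <- quick_fit(series, 2)
  expect_true(fit$converged)
  expect_rel_equal(tidy(fit)$dH_kcal_mol[2], 5.4, 0.01)
  expect_rel_equal(tidy(fit)$dS_cal_mol_K[2], 18, 0.01)
  expect_lt(fit$residual_R, 1e-6)
})

test_that("variable projection is self-consistent at the optimum", {
  series <- exact_series(two_state_model())
  fit <- quick_fit(series, 2)
  cd <- series_matrix(series)
  P <- fit$theory_coefficients
  S2 <- solve_species_spectra(cd, P, fit$weights)
  expect_lt(abs(residual_R(cd, P, S2, fit$weights) - fit$residual_R), 1e-10)
})

test_that("objective is invariant to rescaling the data", {
  series <- exact_series(two_state_model())
  scaled <- series
  scaled$cd <- scaled$cd * 137
  f1 <- quick_fit(series, 2)
  f2 <- quick_fit(scaled, 2)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-6)
  expect_equal(tidy(f1)$dH_kcal_mol, tidy(f2)$dH_kcal_mol, tolerance = 1e-4)
})

test_that("lambda = 0 MAP fit equals the unregularized fit exactly", {
  series <- exact_series(two_state_model())
  prior <- make_basis_spectra(default_band_models()[1:2], quick_grid())$cd
  f0 <- quick_fit(series, 2, lambda = 0, prior_basis = prior)
  f_plain <- quick_fit(series, 2, prior_basis = NULL)
  expect_identical(f0$objective, f_plain$objective)
  expect_identical(tidy(f0), tidy(f_plain))
})

test_that("back-fit of model-generated data equals theoretical populations", {
  series <- exact_series(three_state_model())
  P <- population_matrix(three_state_model(), quick_temps())
  basis <- make_basis_spectra(default_band_models(), quick_grid())$cd
  S <- vapply(basis, function(b) b$value, numeric(length(quick_grid())))
  B <- back_fit_coefficients(series, S)
  expect_lt(max(abs(B - P)), 1e-8)
})

test_that("a constant spectrum at all temperatures is flagged degenerate", {
  wl <- quick_grid()
  cd <- matrix(rep(exp(-(wl - 210)^2 / 100), 15), length(wl), 15)
  series <- spectral_series(wl, quick_temps(), cd)
  expect_warning(fit <- quick_fit(series, 2), "degenerate|collinear|bound")
  expect_true(fit$degenerate)
})

test_that("auto weights need an absorbance block", {
  series <- spectral_series(quick_grid(), quick_temps(),
                            matrix(1, length(quick_grid()), 15) +
                              outer(quick_grid(), 1:15) / 1e4)
  expect_error(fit_global(series, weights = "auto", n_starts = 2),
               "absorbance")
})

test_that("extrapolation composes populations with pure spectra", {
  series <- exact_series(two_state_model())
  fit <- quick_fit(series, 2)
  # at the fitted midpoint the two-state mixture is the plain mean
  tm <- 1000 * tidy(fit)$dH_kcal_mol[2] / tidy(fit)$dS_cal_mol_K[2]
  mid <- extrapolate_spectrum(fit, tm)
  expect_equal(mid$value, rowMeans(fit$pure_spectra), tolerance = 1e-8)
  # compositional identity at an arbitrary temperature
  ex <- extrapolate_spectrum(fit, 283.15)
  p <- boltzmann_populations(fit$model, 283.15)
  expect_equal(ex$value, as.vector(fit$pure_spectra %*% p), tolerance = 1e-12)
  # infinite-temperature limit is the equal-weights mixture
  series3 <- exact_series(three_state_model())
  fit3 <- quick_fit(series3, 3)
  inf3 <- extrapolate_spectrum(fit3, "infinite")
  expect_equal(inf3$value, rowMeans(fit3$pure_spectra), tolerance = 1e-10)
})

test_that("tidiers expose parameters and fit diagnostics", {
  series <- exact_series(two_state_model())
  fit <- quick_fit(series, 2)
  td <- tidy(fit)
  expect_named(td, c("species", "dH_kcal_mol", "dS_cal_mol_K", "midpoint_K"))
  expect_equal(td$species, c("disordered", "beta_turn"))
  gl <- glance(fit)
  expect_equal(gl$n_species, 2)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
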