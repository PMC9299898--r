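# Synthetic temperature-resolved CD/absorbance series.
#
# Species spectra are sums of Gaussian bands whose centers, widths and signs
# reproduce the canonical far-UV signatures: disordered polypeptide (strong
# negative ~197 nm, weak negative shoulder ~220 nm), type-II beta-turn
# (positive ~195 nm, negative ~222 nm), and an "assembly" species with
# negative features at both ~200 and ~225 nm. Series are Boltzmann mixtures
# of these spectra plus Gaussian noise and, optionally, a scattering
# distortion block emulating phase separation above the inverse temperature
# transition.

.gauss_sum <- function(grid, bands) {
  v <- numeric(length(grid))
  for (i in seq_len(nrow(bands)))
    v <- v + bands$amplitude[i] *
      exp(-(grid - bands$center[i])^2 / (2 * bands$sigma[i]^2))
  v
}

.band_tbl <- function(center, sigma, amplitude)
  tibble::tibble(center = center, sigma = sigma, amplitude = amplitude)

#' Default Gaussian band models for the three conformational species
#'
#' Band positions and signs follow the textbook far-UV CD signatures of the
#' species involved in the coil-to-turn transition of elastin-like
#' polypeptides. The beta-turn 222 nm band amplitude is adjusted analytically
#' so that the disordered and beta-turn CD spectra intersect exactly at
#' 213 nm; every two-species mixture therefore passes through an isodichroic
#' point there, as a genuinely two-state temperature series must. Amplitudes
#' are order-of-magnitude conventional for per-residue polypeptide CD
#' (delta-epsilon of a few M^-1 cm^-1); absorptivity bands place the backbone
#' pi-pi* transition near 190-197 nm with a weak n-pi* band near 215-222 nm.
#'
#' @return Named list (`disordered`, `beta_turn`, `assembly`) of band models:
#'   each a list with `label`, `cd_bands`, `abs_bands` tibbles
#'   (`center`/`sigma` in nm, `amplitude` in delta-epsilon or molar
#'   absorptivity units).
#' @export
default_band_models <- function() {
  dis_cd <- .band_tbl(c(197, 220), c(9, 9), c(-10.5, -1.8))
  turn_cd <- .band_tbl(c(195, 222), c(8, 9.5), c(4.0, -6.0))
  # force the isodichroic point: match the two CD spectra exactly at 213 nm
  at <- function(b, x) .gauss_sum(x, b)
  gap <- at(dis_cd, 213) -
    (turn_cd$amplitude[1] * exp(-(213 - 195)^2 / (2 * 8^2)))
  turn_cd$amplitude[2] <- gap / exp(-(213 - 222)^2 / (2 * 9.5^2))
  list(
    disordered = list(label = "disordered", cd_bands = dis_cd,
                      abs_bands = .band_tbl(c(192, 215), c(10, 12),
                                            c(5500, 300))),
    beta_turn = list(label = "beta_turn", cd_bands = turn_cd,
                     abs_bands = .band_tbl(c(197, 222), c(11, 10),
                                           c(5000, 700))),
    assembly = list(label = "assembly",
                    cd_bands = .band_tbl(c(200, 225), c(10, 10), c(-6, -4)),
                    abs_bands = .band_tbl(200, 12, 5200))
  )
}

#' Evaluate band models into basis spectra on a grid
#'
#' @param models Named list of band models (see [default_band_models()]).
#' @param grid Wavelength grid, nm.
#' @return List with elements `cd` and `absorbance`, each a named list of
#'   [basis_spectrum()] objects.
#' @export
make_basis_spectra <- function(models, grid = default_grid()) {
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "label")
  cd <- purrr::map(models, function(m)
    basis_spectrum(grid, .gauss_sum(grid, m$cd_bands), m$label, "cd"))
  ab <- purrr::map(models, function(m)
    basis_spectrum(grid, .gauss_sum(grid, m$abs_bands), m$label, "absorbance"))
  list(cd = cd, absorbance = ab)
}

#' Synthetic-series specification presets
#'
#' Encapsulates the study conditions for the three chain lengths of the
#' (VPGVG)_n elastin-like polypeptide: the fitted two- or three-state
#' thermodynamic parameters, the matching species count, the 10-80 degC
#' temperature ramp in 2 K steps, and (for the phase-separating 40- and
#' 60-repeat constructs) a scattering-distortion block whose onset sits at
#' the construct's inverse temperature transition (333 K for the 40-mer,
#' 315 K for the 60-mer, where a marked CD intensity decrease sets in).
#'
#' @param preset `"vpgvg20"`, `"vpgvg40"` or `"vpgvg60"`.
#' @param noise_sigma Relative Gaussian noise (fraction of max |signal|).
#' @param scattering Include the preset's scattering-distortion block
#'   (ignored for `"vpgvg20"`, which stays in solution over the whole ramp).
#' @param seed Integer seed controlling all randomness of the generator.
#' @return A list (class `cd_synth_spec`) with fields `thermo`,
#'   `band_models`, `temperatures`, `noise_sigma`, `scattering` (NULL or a
#'   distortion block), `seed`, `meta`.
#' @export
synthetic_preset <- function(preset = c("vpgvg20", "vpgvg40", "vpgvg60"),
                             noise_sigma = 0, scattering = TRUE, seed = 42) {
  preset <- match.arg(preset)
  bm <- default_band_models()
  temps <- seq(283.15, 353.15, by = 2)
  params <- switch(preset,
    vpgvg20 = list(thermo = thermo_model(c("disordered", "beta_turn"),
                                         c(0, 5.4), c(0, 18)),
                   models = bm[c("disordered", "beta_turn")],
                   onset = NULL, n_repeats = 20),
    vpgvg40 = list(thermo = thermo_model(c("disordered", "beta_turn", "assembly"),
                                         c(0, 9.9, 89.1), c(0, 33, 270)),
                   models = bm, onset = 333, n_repeats = 40),
    vpgvg60 = list(thermo = thermo_model(c("disordered", "beta_turn", "assembly"),
                                         c(0, 11.2, 158), c(0, 36, 345)),
                   models = bm, onset = 315, n_repeats = 60))
  distort <- NULL
  if (isTRUE(scattering) && !is.null(params$onset)) {
    distort <- list(onset_K = params$onset, rate_per_K = 0.5,
                    scatter_amplitude = 1.5, scatter_mix = c(0.5, 0.5),
                    loss_per_K = 0.008, turbidity_amplitude = 800)
  }
  structure(list(thermo = params$thermo, band_models = params$models,
                 temperatures = temps, noise_sigma = noise_sigma,
                 scattering = distort, seed = seed,
                 meta = list(construct = toupper(preset),
                             n_repeats = params$n_repeats, seed = seed)),
            class = "cd_synth_spec")
}

#' Generate a synthetic temperature-resolved spectral series
#'
#' Builds `cd[, t] = sum_i p_i(T_t) * S_i + noise` with Boltzmann populations
#' from the spec's thermodynamic model and Gaussian-band species spectra
#' (absorbance analogously, from the achiral absorptivity bands). Noise is
#' additive Gaussian with standard deviation `noise_sigma * max|signal|`.
#' When the spec carries a scattering block, the series is then passed
#' through [apply_scattering_distortion()]. Deterministic for a given seed.
#'
#' @param spec A [synthetic_preset()] or hand-built specification list.
#' @param grid Wavelength grid, nm.
#' @return A [spectral_series()] with CD and absorbance blocks.
#' @export
generate_series <- function(spec, grid = default_grid()) {
  basis <- make_basis_spectra(spec$band_models, grid)
  S <- vapply(basis$cd, function(b) b$value, numeric(length(grid)))
  A <- vapply(basis$absorbance, function(b) b$value, numeric(length(grid)))
  P <- population_matrix(spec$thermo, spec$temperatures)
  cd <- S %*% t(P)
  ab <- A %*% t(P)
  .with_seed(spec$seed, {
    if (spec$noise_sigma > 0) {
      cd <- cd + stats::rnorm(length(cd), sd = spec$noise_sigma * max(abs(cd)))
      ab <- ab + stats::rnorm(length(ab), sd = spec$noise_sigma * max(abs(ab)))
    }
  })
  series <- spectral_series(grid, spec$temperatures, cd, ab, spec$meta)
  if (!is.null(spec$scattering)) {
    scb <- scattering_basis_set(
      spec$band_models[c("disordered", "beta_turn")], grid)
    series <- apply_scattering_distortion(series, spec$scattering, scb)
  }
  series
}

#' Apply an above-transition scattering distortion to a series
#'
#' Emulates what phase separation does to suspension spectra: above the onset
#' temperature, CD columns gain an additive differential-scattering
#' contribution whose amplitude grows logistically with `T - onset`, and both
#' CD and absorbance lose intensity uniformly (`1 - loss_per_K * (T - onset)`,
#' floored at 0) as aggregated material precipitates out of the beam.
#' Absorbance columns additionally gain a `lambda^-4` turbidity tail, so that
#' their cosine similarity to the clean low-temperature reference decreases
#' monotonically above onset -- the signal [scattering_weights()] keys on.
#'
#' @param series A `cd_series` with an absorbance block.
#' @param distortion List with `onset_K`, `rate_per_K`, `scatter_amplitude`
#'   (delta-epsilon units), `scatter_mix` (weights over `scatter_basis`),
#'   `loss_per_K`, `turbidity_amplitude` (absorbance units at the short-
#'   wavelength end).
#' @param scatter_basis List of scattering [basis_spectrum()] objects.
#' @return The distorted series.
#' @export
apply_scattering_distortion <- function(series, distortion, scatter_basis) {
  wl <- series_wavelengths(series)
  tk <- series_temperatures(series)
  if (distortion$onset_K < min(tk) || distortion$onset_K > max(tk))
    stop("scattering onset outside the temperature range", call. = FALSE)
  cd <- series_matrix(series, "cd")
  ab <- series_matrix(series, "absorbance")
  mix <- distortion$scatter_mix %||% rep(1 / length(scatter_basis),
                                         length(scatter_basis))
  sc <- Reduce(`+`, Map(function(b, m) m * resample_to_grid(b, wl)$value,
                        scatter_basis, mix))
  turb <- (wl / min(wl))^-4
  for (j in seq_along(tk)) {
    dT <- tk[j] - distortion$onset_K
    if (dT <= 0) next
    amp <- 1 / (1 + exp(-distortion$rate_per_K * dT)) - 0.5  # 0 at onset
    loss <- max(0, 1 - distortion$loss_per_K * dT)
    cd[, j] <- (cd[, j] + 2 * amp * distortion$scatter_amplitude * sc) * loss
    ab[, j] <- ab[, j] * loss + 2 * amp * distortion$turbidity_amplitude * turb
  }
  spectral_series(wl, tk, cd, ab, series_meta(series))
}
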