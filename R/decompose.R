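# Decomposition of an above-transition suspension CD spectrum into a "true
# CD" (difference-absorbance) portion and a differential-scattering portion.
#
# Four basis spectra -- disordered and beta-turn CD, disordered and beta-turn
# differential scattering -- are fitted linearly (NNLS by default) to the
# observed spectrum. The coefficient ratios disordered:beta_turn within each
# portion estimate the conformational composition of the suspension.

#' Decompose a suspension CD spectrum into absorbance and scattering portions
#'
#' Solves the 4-component linear least-squares problem
#' `observed ~ a1*cd_dis + a2*cd_turn + b1*s_dis + b2*s_turn`, nonnegatively
#' by default. Basis columns are l2-normalized for conditioning and the
#' coefficients rescaled back to the original basis amplitudes, so each
#' coefficient is "amount of that species' unit spectrum" and the ratios
#' match their conventional reading.
#'
#' @param observed `cd_basis` (kind `"cd"`): the above-transition spectrum.
#' @param cd_basis List of 2 `cd_basis` CD spectra (disordered, beta-turn).
#' @param scatter_basis List of 2 `cd_basis` scattering spectra (same order).
#' @param nonneg Constrain coefficients to be nonnegative (default TRUE).
#' @return Object of class `cd_decomposition`: list with `coefficients`
#'   (named: `disordered_cd`, `beta_turn_cd`, `disordered_scatter`,
#'   `beta_turn_scatter`), `spectra` (tibble: wavelength, observed, fitted,
#'   absorbance_portion, scattering_portion), `residual_R`,
#'   `ratio_absorbance`, `ratio_scattering`.
#' @export
#' @examples
#' grid <- default_grid()
#' bm <- default_band_models()
#' cdb <- make_basis_spectra(bm[1:2], grid)$cd
#' scb <- scattering_basis_set(bm[1:2], grid)
#' obs <- basis_spectrum(grid, 1.8 * cdb[[1]]$value + 1.0 * cdb[[2]]$value +
#'                         0.5 * scb[[1]]$value + 0.5 * scb[[2]]$value,
#'                       "observed_80C")
#' dec <- decompose_suspension_spectrum(obs, cdb, scb)
#' structure_ratio(dec, "absorbance")
decompose_suspension_spectrum <- function(observed, cd_basis, scatter_basis,
                                          nonneg = TRUE) {
  if (length(cd_basis) != 2 || length(scatter_basis) != 2)
    stop("need exactly 2 CD and 2 scattering basis spectra", call. = FALSE)
  grid <- observed$wavelength_nm
  bases <- c(lapply(cd_basis, resample_to_grid, grid = grid),
             lapply(scatter_basis, resample_to_grid, grid = grid))
  B <- vapply(bases, function(b) b$value, numeric(length(grid)))
  colnames(B) <- c("disordered_cd", "beta_turn_cd",
                   "disordered_scatter", "beta_turn_scatter")
  y <- observed$value
  if (all(y == 0))
    stop("all-zero observed spectrum: normalization undefined", call. = FALSE)
  norms <- sqrt(colSums(B^2))
  if (any(norms == 0) || rcond(crossprod(sweep(B, 2, norms, "/"))) < 1e-10)
    stop("basis matrix is rank deficient", call. = FALSE)
  Bn <- sweep(B, 2, norms, "/")
  coef_n <- if (nonneg) pracma::lsqnonneg(Bn, y)$x else qr.solve(Bn, y)
  coefs <- stats::setNames(coef_n / norms, colnames(B))

  fitted_abs <- as.vector(B[, 1:2] %*% coefs[1:2])
  fitted_sca <- as.vector(B[, 3:4] %*% coefs[3:4])
  fitted <- fitted_abs + fitted_sca
  R <- sqrt(sum((y - fitted)^2) / sum(y^2))

  ratio <- function(num, den) if (coefs[den] < 1e-9) NaN
                              else unname(coefs[num] / coefs[den])
  structure(list(
    coefficients = coefs,
    spectra = tibble::tibble(
      wavelength_nm = grid, observed = y, fitted = fitted,
      absorbance_portion = fitted_abs, scattering_portion = fitted_sca),
    residual_R = R,
    ratio_absorbance = ratio("disordered_cd", "beta_turn_cd"),
    ratio_scattering = ratio("disordered_scatter", "beta_turn_scatter"),
    nonneg = nonneg
  ), class = "cd_decomposition")
}

#' Disordered:beta-turn coefficient ratio of a decomposition portion
#'
#' @param result A `cd_decomposition`.
#' @param regime `"absorbance"` (the difference-absorbance / true-CD portion)
#'   or `"scattering"` (the differential-scattering portion).
#' @return The disordered / beta-turn coefficient ratio. Reported values are
#'   conventionally quoted rounded to one decimal (e.g. "1.8:1.0").
#' @export
structure_ratio <- function(result, regime = c("absorbance", "scattering")) {
  regime <- match.arg(regime)
  r <- if (regime == "absorbance") result$ratio_absorbance
       else result$ratio_scattering
  if (!is.finite(r))
    stop(sprintf("%s-portion ratio undefined: beta-turn coefficient is (near) zero",
                 regime), call. = FALSE)
  r
}

#' @export
print.cd_decomposition <- function(x, ...) {
  cat("Suspension-spectrum decomposition (4 components",
      if (x$nonneg) ", NNLS" else "", ")\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("residual R = %.4g\n", x$residual_R))
  cat(sprintf("disordered:beta-turn  absorbance %.1f:1.0   scattering %.1f:1.0\n",
              x$ratio_absorbance, x$ratio_scattering))
  invisible(x)
}
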