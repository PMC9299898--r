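# Kramers-Kronig transformation and differential-scattering basis spectra.
#
# The KK relations link the absorptive and dispersive parts of a linear
# response and are exact in the frequency domain, so the transform here runs
# in wavenumber (nu = 1e7 / lambda_nm, cm^-1): the spectrum is resampled
# onto a uniform nu grid, zero-padded with a linear edge taper to control
# finite-bandwidth truncation, and the principal-value integral is evaluated
# by Maclaurin's method (summing only grid points of opposite parity, which
# steps over the singularity without special-casing it).

#' Kramers-Kronig conjugate of an absorptivity spectrum
#'
#' Computes the dispersive counterpart of an absorption-mode spectrum: for a
#' molar absorptivity spectrum this is (up to scale) the refractive-index
#' increment; for a CD (difference-absorptivity) spectrum it is the
#' ORD-equivalent difference-index spectrum. Normal-dispersion sign
#' convention: an isolated positive absorption band produces a positive
#' dispersive lobe on its long-wavelength side.
#'
#' @param absorptivity A `cd_basis` (any kind) or data frame with columns
#'   `wavelength_nm`, `value`, on a uniform wavelength grid with at least 16
#'   points.
#' @param pad_factor Integer >= 2; the uniform wavenumber grid is extended to
#'   `pad_factor` times its length with zeros (after a linear taper over the
#'   first 10% of each padded flank) before the transform.
#' @return Numeric vector: the KK-conjugate spectrum on the input wavelength
#'   grid.
#' @export
#' @examples
#' wl <- seq(185, 260, 0.5)
#' band <- basis_spectrum(wl, exp(-(wl - 222)^2 / (2 * 6^2)), "beta_turn")
#' disp <- kramers_kronig(band)
kramers_kronig <- function(absorptivity, pad_factor = 4) {
  wl <- absorptivity$wavelength_nm
  f <- absorptivity$value
  n <- length(wl)
  if (n < 16) stop("need at least 16 points for the transform", call. = FALSE)
  if (pad_factor < 2) stop("pad_factor must be >= 2", call. = FALSE)
  steps <- diff(wl)
  if (any(steps <= 0)) stop("wavelengths must be strictly ascending", call. = FALSE)
  if (max(steps) / min(steps) > 1 + 1e-6)
    stop("wavelength grid must be uniform", call. = FALSE)

  # wavelength -> wavenumber (ascending), oversampled 4x so the
  # principal-value kernel is well resolved even for narrow bands
  nu_src <- rev(1e7 / wl)
  f_src <- rev(f)
  n_nu <- 4L * n
  nu <- seq(nu_src[1], nu_src[n], length.out = n_nu)
  fu <- stats::approx(nu_src, f_src, xout = nu)$y

  # symmetric zero padding with linear taper over 10% of each pad
  h <- nu[2] - nu[1]
  n_pad <- ceiling((pad_factor - 1) * n_nu / 2)
  taper_len <- max(1L, floor(0.1 * n_pad))
  left <- c(rep(0, n_pad - taper_len),
            seq(0, fu[1], length.out = taper_len + 1)[-(taper_len + 1)])
  right <- c(seq(fu[n_nu], 0, length.out = taper_len + 1)[-1],
             rep(0, n_pad - taper_len))
  fp <- c(left, fu, right)
  nup <- seq(nu[1] - n_pad * h, by = h, length.out = length(fp))
  N <- length(fp)

  # Maclaurin's method: g(nu_i) = (2h/pi) * sum_{j: i+j odd} f_j/(nu_j - nu_i)
  idx <- seq_len(N)
  parity <- idx %% 2L
  g <- numeric(N)
  core <- (n_pad + 1):(n_pad + n_nu)      # only need the data region
  for (i in core) {
    j <- which(parity != parity[i])
    g[i] <- sum(fp[j] / (nup[j] - nup[i]))
  }
  g <- g * (2 * h / pi)

  # back to the lambda grid; this sign gives normal dispersion (positive lobe
  # on the long-wavelength / low-nu side of a positive band)
  gl <- stats::approx(nu, g[core], xout = nu_src)$y
  rev(gl)
}

#' Refractive-index gradient spectra of a species
#'
#' Applies the Kramers-Kronig transform to the molar absorptivity spectrum
#' (giving `dn/dc`, the refractive-index gradient with particle
#' concentration) and to the molar difference-absorptivity (CD) spectrum
#' (giving `dDn/dc`, the circular-difference index gradient -- the
#' ORD-equivalent spectrum, which is why scattering distortions of suspension
#' CD resemble an ORD curve).
#'
#' @param cd_basis `cd_basis` of kind `"cd"` (delta-epsilon).
#' @param abs_basis `cd_basis` of kind `"absorbance"` (molar absorptivity),
#'   same grid.
#' @param pad_factor Passed to [kramers_kronig()].
#' @return A tibble of class `refractive_gradient` with columns
#'   `wavelength_nm`, `dn_dc`, `dDn_dc`; the species label is kept in the
#'   `source_label` attribute.
#' @export
refractive_gradients <- function(cd_basis, abs_basis, pad_factor = 4) {
  if (length(cd_basis$wavelength_nm) != length(abs_basis$wavelength_nm) ||
      max(abs(cd_basis$wavelength_nm - abs_basis$wavelength_nm)) > 1e-9)
    stop("CD and absorptivity spectra must share a wavelength grid",
         call. = FALSE)
  structure(tibble::tibble(
    wavelength_nm = cd_basis$wavelength_nm,
    dn_dc = kramers_kronig(abs_basis, pad_factor),
    dDn_dc = kramers_kronig(cd_basis, pad_factor)
  ), source_label = basis_label(cd_basis),
     class = c("refractive_gradient", class(tibble::tibble())))
}

#' Differential-scattering basis spectrum of a species
#'
#' Builds the apparent-CD contribution from preferential scattering of one
#' circular polarization by suspended particles. In the Rayleigh-Gans-Debye
#' regime the differential scattering cross-section is bilinear in the
#' ordinary and circular-difference index gradients, so the basis spectrum is
#' modelled as `Ds(lambda) = K * dn_dc * dDn_dc / lambda^2` (the
#' `"rgd_product"` model; the `lambda^-2` prefactor, switchable via
#' `lambda_power = 0`, makes scattering grow toward short wavelengths as
#' observed in turbid suspensions). The overall scale `K` is arbitrary --
#' basis spectra enter the decomposition only up to their linear
#' coefficients -- and is fixed here by normalizing the peak magnitude to 1.
#'
#' @param grad A [refractive_gradients()] result.
#' @param model Scattering model; only `"rgd_product"` is implemented.
#' @param lambda_power Exponent of the `1/lambda` prefactor (default 2).
#' @return A [basis_spectrum()] of kind `"scattering"`.
#' @export
differential_scattering_basis <- function(grad, model = "rgd_product",
                                          lambda_power = 2) {
  model <- match.arg(model, "rgd_product")
  v <- grad$dn_dc * grad$dDn_dc / grad$wavelength_nm^lambda_power
  peak <- max(abs(v))
  if (peak > 0) v <- v / peak
  basis_spectrum(grad$wavelength_nm, v,
                 label = attr(grad, "source_label") %||% "scattering",
                 kind = "scattering")
}

#' Scattering basis spectra for a set of species band models
#'
#' Convenience wrapper running the full chain CD/absorptivity basis ->
#' refractive gradients -> differential-scattering basis per species.
#'
#' @param models Named list of band models (see [default_band_models()]).
#' @param grid Wavelength grid.
#' @param pad_factor Passed to [kramers_kronig()].
#' @param lambda_power Passed to [differential_scattering_basis()].
#' @return Named list of scattering [basis_spectrum()] objects.
#' @export
scattering_basis_set <- function(models, grid = default_grid(),
                                 pad_factor = 4, lambda_power = 2) {
  out <- purrr::map(models, function(bm) {
    cdb <- make_basis_spectra(list(bm), grid)$cd[[1]]
    abb <- make_basis_spectra(list(bm), grid)$absorbance[[1]]
    differential_scattering_basis(
      refractive_gradients(cdb, abb, pad_factor),
      lambda_power = lambda_power)
  })
  stats::setNames(out, names(models))
}
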