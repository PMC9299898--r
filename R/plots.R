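# ggplot2 quick-look plots for the main result types.

#' @method autoplot cd_series
#' @export
autoplot.cd_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$cd,
                               colour = .data$temperature_K - 273.15,
                               group = .data$temperature_K)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "T (°C)", option = "plasma") +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(Delta * epsilon ~ "(M"^-1 * "cm"^-1 * ")")) +
    ggplot2::theme_minimal()
}

#' @method autoplot cd_basis
#' @export
autoplot.cd_basis <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm,
                                       y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = basis_kind(object),
                  title = basis_label(object)) +
    ggplot2::theme_minimal()
}

#' @method autoplot cd_global_fit
#' @export
autoplot.cd_global_fit <- function(object, ...) {
  S <- object$pure_spectra
  spec_tbl <- tibble::tibble(
    wavelength_nm = rep(object$wavelengths, times = ncol(S)),
    species = rep(colnames(S), each = nrow(S)),
    value = as.vector(S))
  p1 <- ggplot2::ggplot(spec_tbl,
                        ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "pure-species Δε") +
    ggplot2::theme_minimal()
  curves <- coefficient_curves(object)
  p2 <- ggplot2::ggplot(curves,
                        ggplot2::aes(x = .data$temperature_K - 273.15,
                                     y = .data$coefficient,
                                     colour = .data$species,
                                     linetype = .data$kind)) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$kind == "theory")) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$kind == "backfit")) +
    ggplot2::labs(x = "temperature (°C)", y = "coefficient") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE))
    patchwork::wrap_plots(p1, p2, ncol = 2)
  else
    p2
}

#' @method autoplot cd_decomposition
#' @export
autoplot.cd_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(object$spectra, -"wavelength_nm",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "Δε (apparent)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
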