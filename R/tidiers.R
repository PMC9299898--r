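# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a global fit: one row per species
#'
#' @param x A `cd_global_fit`.
#' @param ... Unused.
#' @return Tibble with `species`, `dH_kcal_mol`, `dS_cal_mol_K`,
#'   `midpoint_K` (NA for the reference species).
#' @method tidy cd_global_fit
#' @export
tidy.cd_global_fit <- function(x, ...) {
  m <- tibble::as_tibble(x$model)
  m$midpoint_K <- ifelse(m$dS_cal_mol_K == 0, NA_real_,
                         1000 * m$dH_kcal_mol / m$dS_cal_mol_K)
  m
}

#' One-row fit summary
#'
#' @param x A `cd_global_fit`.
#' @param ... Unused.
#' @method glance cd_global_fit
#' @export
glance.cd_global_fit <- function(x, ...) {
  tibble::tibble(n_species = nrow(x$model),
                 n_wavelengths = length(x$wavelengths),
                 n_temperatures = length(x$temperatures),
                 residual_R = x$residual_R,
                 objective = x$objective,
                 lambda = x$lambda,
                 converged = x$converged,
                 degenerate = x$degenerate,
                 at_bounds = x$at_bounds,
                 n_evaluations = x$n_evaluations)
}

#' Tidy a suspension-spectrum decomposition: one row per basis component
#'
#' @param x A `cd_decomposition`.
#' @param ... Unused.
#' @method tidy cd_decomposition
#' @export
tidy.cd_decomposition <- function(x, ...) {
  tibble::tibble(component = names(x$coefficients),
                 species = sub("_(cd|scatter)$", "", names(x$coefficients)),
                 portion = ifelse(grepl("_cd$", names(x$coefficients)),
                                  "absorbance", "scattering"),
                 coefficient = unname(x$coefficients))
}

#' One-row decomposition summary
#'
#' @param x A `cd_decomposition`.
#' @param ... Unused.
#' @method glance cd_decomposition
#' @export
glance.cd_decomposition <- function(x, ...) {
  tibble::tibble(residual_R = x$residual_R,
                 ratio_absorbance = x$ratio_absorbance,
                 ratio_scattering = x$ratio_scattering,
                 nonneg = x$nonneg)
}

#' Coefficient curves of a global fit as a long tibble
#'
#' Combines the theoretical Boltzmann populations with the back-fitted
#' empirical coefficients for plotting or inspection.
#'
#' @param fit A `cd_global_fit`.
#' @return Tibble with `temperature_K`, `species`, `kind`
#'   (`"theory"`/`"backfit"`), `coefficient`.
#' @export
coefficient_curves <- function(fit) {
  long <- function(M, kind) tibble::tibble(
    temperature_K = rep(fit$temperatures, times = ncol(M)),
    species = rep(colnames(M), each = nrow(M)),
    kind = kind,
    coefficient = as.vector(M))
  dplyr::bind_rows(long(fit$theory_coefficients, "theory"),
                   long(fit$backfit_coefficients, "backfit"))
}
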