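# Boltzmann population model over conformational species.
#
# Each non-reference species i carries a transition enthalpy dH_i (kcal/mol)
# and entropy dS_i (cal/mol/K) relative to the reference (disordered) species,
# giving dG_i(T) = 1000*dH_i - T*dS_i in cal/mol. Populations follow a
# Boltzmann distribution over the dG_i; because the parameters are molar, the
# molar gas constant R replaces the per-molecule Boltzmann constant.

#' Molar gas constant in cal mol^-1 K^-1
#' @export
R_GAS_CAL <- 1.987204

#' Construct a conformational-species thermodynamic model
#'
#' The first species is the reference and must have `dH = dS = 0`; the
#' remaining species carry transition enthalpies/entropies relative to it.
#' Enthalpies are in kcal mol^-1, entropies in cal mol^-1 K^-1 (the units in
#' which such parameters are conventionally tabulated); internal energies are
#' handled in cal mol^-1.
#'
#' @param species Character vector of unique species labels (length 2 or 3);
#'   first label is the reference, conventionally `"disordered"`.
#' @param dH_kcal Transition enthalpies, kcal mol^-1 (first must be 0).
#' @param dS_cal Transition entropies, cal mol^-1 K^-1 (first must be 0).
#' @return A tibble of class `thermo_model` with columns `species`,
#'   `dH_kcal_mol`, `dS_cal_mol_K`.
#' @export
#' @examples
#' m <- thermo_model(c("disordered", "beta_turn"), c(0, 5.4), c(0, 18))
#' boltzmann_populations(m, 283.15)
thermo_model <- function(species, dH_kcal, dS_cal) {
  M <- length(species)
  if (!M %in% c(2L, 3L)) stop("model must have 2 or 3 species", call. = FALSE)
  if (anyDuplicated(species)) stop("species labels must be unique", call. = FALSE)
  if (length(dH_kcal) != M || length(dS_cal) != M)
    stop("dH_kcal and dS_cal must match the number of species", call. = FALSE)
  if (dH_kcal[1] != 0 || dS_cal[1] != 0)
    stop("reference species (first) must have dH = dS = 0", call. = FALSE)
  if (any(!is.finite(dH_kcal)) || any(!is.finite(dS_cal)))
    stop("non-finite thermodynamic parameters", call. = FALSE)
  if (any(abs(dH_kcal) > 1e3) || any(abs(dS_cal) > 1e4))
    stop("parameters outside sanity bounds (|dH| <= 1e3 kcal/mol, |dS| <= 1e4 cal/mol/K)",
         call. = FALSE)
  structure(tibble::tibble(species = as.character(species),
                           dH_kcal_mol = as.numeric(dH_kcal),
                           dS_cal_mol_K = as.numeric(dS_cal)),
            class = c("thermo_model", class(tibble::tibble())))
}

#' Gibbs free energy of a species relative to the reference
#'
#' `dG = 1000*dH - T*dS` in cal mol^-1, with dH and dS treated as
#' temperature-independent.
#'
#' @param dH_kcal Transition enthalpy, kcal mol^-1.
#' @param dS_cal Transition entropy, cal mol^-1 K^-1.
#' @param T_K Temperature(s), kelvin, positive.
#' @return Free energy in cal mol^-1 (vectorised over `T_K`).
#' @export
gibbs_free_energy <- function(dH_kcal, dS_cal, T_K) {
  if (any(T_K <= 0)) stop("temperature must be positive", call. = FALSE)
  1000 * dH_kcal - T_K * dS_cal
}

#' Boltzmann populations of the model species at one temperature
#'
#' `p_i = exp(-dG_i / (R T)) / sum_j exp(-dG_j / (R T))`, computed with
#' max-subtraction so that very large free-energy gaps underflow to zero
#' rather than overflow.
#'
#' @param model A [thermo_model()].
#' @param T_K Temperature, kelvin, positive.
#' @return Named numeric vector of populations summing to 1.
#' @export
boltzmann_populations <- function(model, T_K) {
  if (length(T_K) != 1 || T_K <= 0)
    stop("T_K must be a single positive temperature", call. = FALSE)
  g <- gibbs_free_energy(model$dH_kcal_mol, model$dS_cal_mol_K, T_K)
  x <- -g / (R_GAS_CAL * T_K)
  x <- x - max(x)
  p <- exp(x) / sum(exp(x))
  stats::setNames(p, model$species)
}

#' Population matrix over a temperature vector
#'
#' @param model A [thermo_model()].
#' @param temperatures Kelvin vector, all positive.
#' @return Matrix `[n_temperatures x M]`; each row sums to 1. Columns are
#'   named by species.
#' @export
population_matrix <- function(model, temperatures) {
  P <- t(vapply(temperatures, function(tt) boltzmann_populations(model, tt),
                numeric(nrow(model))))
  dimnames(P) <- list(NULL, model$species)
  P
}

#' Tidy population curves
#'
#' @param model A [thermo_model()].
#' @param temperatures Kelvin vector.
#' @return Long tibble with `temperature_K`, `species`, `population`.
#' @export
population_curves <- function(model, temperatures) {
  P <- population_matrix(model, temperatures)
  tibble::tibble(
    temperature_K = rep(temperatures, times = ncol(P)),
    species = rep(colnames(P), each = length(temperatures)),
    population = as.vector(P)
  )
}

#' Transition midpoint temperature
#'
#' Temperature at which a species' free energy relative to the reference
#' vanishes: `T_mid = 1000*dH/dS` kelvin. At this temperature a two-state
#' model is populated (0.5, 0.5).
#'
#' @inheritParams gibbs_free_energy
#' @return Midpoint temperature, kelvin.
#' @export
midpoint_temperature <- function(dH_kcal, dS_cal) {
  if (any(dS_cal == 0))
    stop("midpoint temperature undefined for dS = 0", call. = FALSE)
  tm <- 1000 * dH_kcal / dS_cal
  if (any(dH_kcal == 0))
    warning("dH = 0 gives a degenerate midpoint at 0 K")
  tm
}
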