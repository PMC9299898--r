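# cdthermo

Thermodynamic global fitting of temperature-resolved circular dichroism
(CD) spectra, built for thermoresponsive polypeptides such as elastin-like
proteins (ELPs).

Heating an ELP like (VPGVG)ₙ drives a conformational transition from
disordered chains toward β-turn structure and, for long enough chains,
phase separation above an inverse temperature transition (ITT). A CD
temperature ramp yields a wavelength × temperature matrix whose columns mix
a few pure-species spectra with temperature-dependent weights. `cdthermo`
resolves that mixture for people who record such ramps: it estimates the
transition thermodynamics, extracts the pure-species spectra, and
disentangles true CD from particle-scattering artifacts above the ITT.

## The model

Species populations follow a Boltzmann distribution over free energies
relative to the disordered reference,

```
p_i(T) = exp(-ΔG_i/RT) / Σ_j exp(-ΔG_j/RT),    ΔG_i = ΔH_i − T·ΔS_i,
```

with ΔH and ΔS temperature-independent. The data matrix is modelled
bilinearly, `D ≈ S·Pᵀ(θ)`, and fitted by matrix least-squares (MLS) global
fitting with variable projection: the nonlinear search runs only over the
2(M−1) thermodynamic parameters while the pure-species spectra `S` are
solved exactly as a weighted linear subproblem at every step. The quality
measure is the normalized residual `R` (0 = perfect fit, 1 = no model).
For phase-separating samples, a maximum-a-posteriori variant down-weights
scattering-contaminated spectra (cosine similarity of the parent absorbance
to a clean reference, raised to the 4th power) and penalizes deviation of
the fitted disordered/β-turn spectra from reference shapes.

Around the fit, the package provides a Kramers–Kronig chain (absorptivity →
refractive-index-gradient spectra → differential-scattering basis spectra
for suspended particles), a 4-component decomposition of above-ITT spectra
into difference-absorbance and scattering portions with disordered:β-turn
coefficient ratios per portion, and a synthetic-data generator whose
presets embed the published (VPGVG)₂₀/₄₀/₆₀ thermodynamic parameters.

## A worked example

```r
library(cdthermo)

spec   <- synthetic_preset("vpgvg20", noise_sigma = 0.01, seed = 7)
series <- generate_series(spec)          # 151 wavelengths x 36 temperatures
fit    <- fit_global(series, n_species = 2)
fit
#> MLS global fit: 2 species, 151 wavelengths x 36 temperatures
#> residual R = 0.02058, objective = 0.0004236, converged = TRUE
#> # A tibble: 2 × 3
#>   species    dH_kcal_mol dS_cal_mol_K
#>   <chr>            <dbl>        <dbl>
#> 1 disordered        0             0
#> 2 beta_turn         5.52         18.4
```

The series was generated with ΔH = 5.4 kcal mol⁻¹ and ΔS = 18
cal mol⁻¹ K⁻¹ plus 1% noise; the fit recovers 5.52 / 18.4 — a 2%
error, typical at this noise level. `residual_R = 0.021` says the two-state
bilinear model explains all but ~2% of the signal's norm, i.e. the noise
floor. `tidy(fit)`, `glance(fit)` and `autoplot(fit)` give the parameter
table (with transition midpoints), one-row diagnostics, and a plot of the
pure-species spectra with theoretical vs back-fitted coefficient curves.

Downstream, `scattering_basis_set()` builds differential-scattering basis
spectra via the Kramers–Kronig transform, and
`decompose_suspension_spectrum()` splits an above-ITT spectrum into its
true-CD and scattering portions:

```r
bm  <- default_band_models()[c("disordered", "beta_turn")]
dec <- decompose_suspension_spectrum(
  extrapolate_spectrum(fit3, "infinite"),       # fit3: a 3-species fit
  make_basis_spectra(bm, fit3$wavelengths)$cd,
  scattering_basis_set(bm, fit3$wavelengths))
structure_ratio(dec, "absorbance")   # disordered : beta-turn in the CD portion
```

## Layout

- `R/` — spectra I/O and containers, thermodynamic model, global fitting,
  Kramers–Kronig/scattering, decomposition, synthetic data, pipeline.
- `vignettes/cd-global-fitting.Rmd` — the methods vignette: model,
  assumptions, numerical choices, generator design, known limits.
- `inst/cli/cdthermo-cli.R` — thin Rscript wrapper with `simulate`, `fit`,
  `kkt`, `decompose`, `run` subcommands.
- `tests/testthat/` — unit, property and acceptance suites.
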