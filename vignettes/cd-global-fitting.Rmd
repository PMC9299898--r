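---
title: "Thermodynamic global fitting of temperature-resolved CD spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic global fitting of temperature-resolved CD spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdthermo)
```

## The problem

Elastin-like polypeptides (ELPs) — repeats of the pentapeptide VPGVG — phase
separate above an inverse temperature transition (ITT): heating drives the
chains from a soluble, largely disordered state into a dense coacervate
phase. Far-UV circular dichroism (CD) tracks the conformational side of this
process, because the disordered state (strong negative band near 195–197 nm)
and the type-II β-turn state (positive ~195 nm, negative ~222 nm) have
distinct, roughly linear-mixing spectra. A temperature ramp therefore yields
a wavelength × temperature data matrix whose columns are mixtures of a small
number of pure-species spectra with temperature-dependent weights.

`cdthermo` implements the full analysis chain for such data:

1. a **Boltzmann population model** over 2 or 3 conformational species,
2. **matrix least-squares (MLS) global fitting** that resolves the transition
   enthalpies/entropies *and* the pure-species spectra simultaneously,
3. a **maximum-a-posteriori (MAP) variant** with per-spectrum weights and
   spectral-shape priors for scattering-contaminated (phase-separating)
   samples,
4. a **Kramers–Kronig (KK) chain** that turns absorptivity and CD spectra
   into refractive-index-gradient spectra and from those builds
   **differential-scattering basis spectra** for suspended particles, and
5. a **4-component decomposition** of an above-ITT suspension spectrum into
   a "true CD" (difference-absorbance) portion and a differential-scattering
   portion, each reported as a disordered:β-turn coefficient ratio.

A synthetic-data module generates series with exactly the statistical
structure the analysis assumes, so every stage is testable without
instrument data.

## The population model

Species populations follow a Boltzmann distribution over free energies
relative to the lowest-lying (disordered) species,

$$p_i(T) = \frac{e^{-\Delta G_i/RT}}{\sum_{j=1}^{M} e^{-\Delta G_j/RT}},
\qquad \Delta G_i = \Delta H_i - T\,\Delta S_i,$$

with $\Delta H_i$ (kcal mol⁻¹) and $\Delta S_i$ (cal mol⁻¹ K⁻¹) treated as
temperature-independent (no heat-capacity term) and the reference species
pinned at $\Delta G \equiv 0$. Because the parameters are molar, the molar
gas constant $R = 1.987204$ cal mol⁻¹ K⁻¹ is used; the distribution is
computed with max-subtraction so large free-energy gaps underflow to zero
instead of overflowing. An entropy-driven transition ($\Delta S_i > 0$)
populates species $i$ with increasing temperature; its midpoint lies at
$T_m = 1000\,\Delta H_i/\Delta S_i$, where a two-state system is exactly
50:50.

Two consequences of this parameterisation are worth spelling out:

* Only free-energy *differences* are observable, and species labels are
  exchangeable. The fit therefore reports results in a fixed gauge: the
  reference slot is re-anchored on whichever fitted species actually
  dominates at the lowest temperature (that is what "lowest-lying" means),
  a free species that remains essentially unpopulated over the whole ramp
  is parked in the assembly slot (it is spectrally unidentifiable), and the
  remaining ambiguity is resolved by spectral signature — the β-turn slot
  takes the column with the larger (positive-band) value near 195 nm.
* With $\Delta G_i = \Delta H_i - T\Delta S_i$ the $T\to\infty$ populations
  tend to $\propto e^{\Delta S_i/R}$, not to $1/M$. The conventional
  "infinite-temperature" extrapolation instead means the limit in which
  free-energy gaps vanish on the $RT$ scale; `extrapolate_spectrum(fit,
  "infinite")` implements that convention as the equal-weights mixture
  $\bar S = S\,(1/M,\dots,1/M)^\top$.

## MLS global fitting by variable projection

Writing the data matrix $D$ (wavelength × temperature) as $D \approx S
P^\top(\theta)$ with $P$ the population matrix and $S$ the pure-species
spectra, the fit minimises the normalized weighted residual

$$R^2(\theta) = \frac{\sum_t w_t \lVert D_{\cdot t} - S^*(\theta)\,
P_t(\theta)\rVert^2}{\sum_t w_t \lVert D_{\cdot t}\rVert^2},$$

where $S^*(\theta)$ is the exact weighted-least-squares solution of the
linear subproblem at the candidate $\theta = \{(\Delta H_i, \Delta
S_i)\}_{i\ge 2}$ (variable projection). This reduces the nonlinear search to
$2(M-1)$ dimensions and is what makes the simultaneous resolution of
$\Delta H$ and $\Delta S$ from a single ramp stable: every wavelength
contributes to the estimate. $R$ is 0 for a perfect fit, 1 for $S = 0$, and
invariant under rescaling the data.

The optimizer is a box-constrained quasi-Newton search (`stats::nlminb`)
from a Latin-hypercube multistart. The start design matters more than the
local method here: a pair $(\Delta H, \Delta S)$ drawn uniformly from the
bound box (defaults $\Delta H \in [0, 400]$ kcal mol⁻¹, $\Delta S \in [0,
1200]$ cal mol⁻¹ K⁻¹, covering reported ELP magnitudes with margin) almost
never places its midpoint $1000\,\Delta H/\Delta S$ inside the measured
window, and a large $\Delta H$ makes the transition sharper than the
temperature grid — in both cases the objective is locally flat and descent
stalls. Starts are therefore drawn per species as (midpoint uniform over
the data range ± a margin, $\Delta H$ log-uniform up to the bound) and
mapped back into the bound box. The defaults are 32 starts with seed 42;
the lowest objective wins (near-ties broken by the lower first-species
$\Delta H$, for determinism) and the winner is re-polished at tight
tolerance. Degenerate parameter regions (near-constant populations) are
handled with a pseudoinverse in the linear subproblem so the objective
stays finite and continuous; a fit whose resolved spectra are nearly
collinear is flagged `degenerate`.

### The MAP variant for phase-separating samples

Above the ITT, suspension spectra are distorted by differential scattering
and intensity loss, and slow equilibration can deplete the solution-phase
species. Two modifications keep the fit anchored:

* **Per-spectrum weights** (`weights = "auto"`): each temperature's weight
  is $w_t = \max(0, \cos(\mathbf{a}_t, \mathbf{a}_\mathrm{ref}))^{\gamma}$,
  the cosine similarity between its parent absorbance spectrum and a clean
  reference (the mean of the coolest quarter of the ramp), normalized to
  max 1. The exponent $\gamma = 4$ is a design choice: a power of the
  cosine is the simplest monotone sharpening, and $\gamma = 4$ down-weights
  a visibly distorted spectrum (cosine ≈ 0.9) about 3.4-fold.
* **A spectral-shape prior** (MAP estimation): the objective becomes
  $R^2 + \lambda \sum_i (1 - \cos(S_i, S_i^\mathrm{ref}))$ over the species
  with reference spectra (disordered and β-turn; the assembly species is
  unconstrained). The prior is scale-free — it constrains shape only, which
  is the defensible reading when reference and sample amplitudes need not
  match — and $\lambda = 0$ reduces exactly to the unregularized fit.
  $\lambda$ defaults to 0.1 on the dimensionless objective; no principled
  value is available, so it is exposed in the interface.

Back-fitting regresses each observed spectrum on the resolved pure spectra
(nonnegative least squares by default), with **no** sum-to-one constraint:
for phase-separating samples the back-fitted totals legitimately fall below
1 above the transition as aggregated material precipitates out of the beam,
and that deviation is diagnostic, not noise.

## The Kramers–Kronig chain and differential scattering

Particles comparable in size to the wavelength scatter left- and
right-circularly polarized light differently, adding an apparent-CD
contribution shaped like the optical rotatory dispersion (ORD) of the
particle material. The KK relations link an absorption-mode spectrum to its
dispersive counterpart; applied to the molar absorptivity this gives the
refractive-index gradient $\partial n/\partial c$, applied to the CD
spectrum the circular-difference gradient $\partial\Delta n/\partial c$
(the ORD-equivalent).

Numerical choices, in order of consequence:

* **Domain.** The transform runs in wavenumber ($\nu = 10^7/\lambda$,
  cm⁻¹), where the KK relations are exact; spectra are resampled onto a
  uniform $\nu$ grid, 4× oversampled so the principal-value kernel stays
  resolved even for bands a few grid steps wide.
* **Quadrature.** Maclaurin's method: the principal-value sum runs only
  over grid points of opposite parity, stepping over the singularity with
  no special-casing, spectrally accurate on uniform grids.
* **Truncation.** The grid is zero-padded to `pad_factor` (default 4) times
  its length, with a linear taper over the first 10% of each padded flank;
  no Lorentzian tail extrapolation is attempted. Doubling the padding
  changes the central 60% of the transform by well under 0.5%. Against a
  closed-form Lorentzian dispersion curve the transform is accurate to
  ~1–2% centrally for bands of half-width ≥ ~500 cm⁻¹; accuracy degrades
  for bands approaching the grid resolution.
* **Sign convention.** Normal dispersion: a positive absorption band gives
  a positive dispersive lobe on its long-wavelength side.

The differential-scattering basis spectrum of a species is then modelled as

$$\Delta s(\lambda) = K\,\frac{\partial n}{\partial c}(\lambda)\,
\frac{\partial \Delta n}{\partial c}(\lambda)\,\lambda^{-2},$$

a Rayleigh–Gans–Debye-motivated bilinear form; the $\lambda^{-2}$ prefactor
(switchable off) makes scattering grow toward short wavelengths as observed
in turbid suspensions. No Mie theory and no explicit particle-size
dependence is attempted, and absorption flattening is out of scope. The
overall scale $K$ is arbitrary because the basis enters the decomposition
only through its linear coefficient; it is fixed by peak-normalizing each
basis spectrum to 1.

## Suspension-spectrum decomposition

An above-ITT spectrum is fitted as a nonnegative linear combination of four
basis spectra — disordered CD, β-turn CD, disordered scattering, β-turn
scattering. Basis columns are ℓ2-normalized for conditioning and the
coefficients rescaled back, so each coefficient means "amount of that
species' unit spectrum" and the two ratios

* `ratio_absorbance` = disordered:β-turn within the difference-absorbance
  ("true CD") portion, and
* `ratio_scattering` = disordered:β-turn within the differential-scattering
  portion

carry the conventional reading. NNLS is the default (the coefficients are
amounts of physical components); an unconstrained fit is available by flag
since the constraint choice cannot be settled from first principles. Ratios
with a β-turn coefficient below 10⁻⁹ are flagged `NaN` rather than
reported.

## The synthetic-data generator

The generator is the package's stand-in for instrument data and encodes the
study conditions:

* **Species spectra** are sums of Gaussian bands with the canonical band
  positions and signs (disordered: strong negative 197 nm, weak negative
  220 nm; β-turn: positive 195 nm, negative 222 nm; assembly: negative
  features at 200 and 225 nm). The β-turn 222 nm amplitude is adjusted
  analytically so the two solution-species spectra intersect exactly at
  213 nm; every two-state mixture then passes through an isodichroic point
  there, as real two-state data do. Amplitudes are order-of-magnitude
  conventional for per-residue polypeptide CD (|Δε| of a few
  M⁻¹ cm⁻¹) and are exposed in the band models; no amplitude scale is
  available to copy, and none of the analysis depends on it (the fit
  objective is scale-invariant).
* **Grids.** 185–260 nm in 0.5 nm steps (151 points); 283.15–353.15 K in
  2 K steps (36 points), i.e. a 10–80 °C ramp.
* **Presets** embed the reported thermodynamic parameters per chain length:
  `vpgvg20` (two-state, ΔH = 5.4, ΔS = 18), `vpgvg40` (three-state,
  9.9/33 and 89.1/270), `vpgvg60` (three-state, 11.2/36 and 158/345);
  kcal mol⁻¹ and cal mol⁻¹ K⁻¹ throughout.
* **Noise** is additive Gaussian with standard deviation `noise_sigma` ×
  max |signal|, a single seed controls all randomness, and the seed is
  recorded in the series metadata.
* **Scattering distortion** (for the phase-separating 40- and 60-repeat
  presets): above an onset temperature (333 K for the 40-mer; 315 K for
  the 60-mer, where a marked intensity decrease sets in), CD columns gain
  an additive differential-scattering contribution with logistic growth in
  $T$, both blocks lose intensity uniformly ($1 - 0.008\,(T -
  T_\mathrm{onset})$, emulating precipitation), and absorbance gains a
  $\lambda^{-4}$ turbidity tail so the similarity weights respond the way
  they would on real turbid samples. The logistic amplitude is a
  phenomenological stand-in, not a kinetic model.

What the generator deliberately does **not** emulate: absorption
flattening, instrument baseline drift, wavelength-dependent noise (real CD
noise grows steeply below ~195 nm where the photomultiplier dynode voltage
rises), and particle-size-dependent scattering shapes. Tests passing on
synthetic data therefore demonstrate the estimator's correctness under the
model's own assumptions — identifiability, convergence, calibration — not
robustness to every instrumental artifact of real ELP data.

## Known limits of identifiability

Two findings from exercising the pipeline at the study's own parameter
values deserve a visible record:

* **The 60-repeat assembly step is unidentifiable on a 10–80 °C ramp.**
  Parameters ΔH₂ = 158 kcal mol⁻¹, ΔS₂ = 345 cal mol⁻¹ K⁻¹ put the
  assembly midpoint at 1000·158/345 ≈ 458 K; under the Boltzmann model the
  assembly population stays below 10⁻²² everywhere on the ramp, so data
  generated from these values contain no assembly signal at double
  precision. A three-species fit of such data has a continuum of
  residual-zero solutions; the gauge-fixing rules above report the
  identifiable interconversion step (ΔH₁, ΔS₁) correctly and park the
  unidentifiable slot, but no method can recover the planted (158, 345)
  from this window. The two-step parameters for the 40-repeat preset
  (midpoints 300 K and 330 K, both in-window) are fully identifiable, and
  are recovered to machine precision from noiseless series.
* **Rounded parameters vs prose percentages.** The reported two-state
  parameters for the 20-repeat construct give ≈37% β-turn at 10 °C and a
  50:50 point at ≈27 °C under the Boltzmann model, not the ≈20% / "above
  70 °C" sometimes quoted alongside them; the implementation follows the
  equation and the tabulated parameters, not the prose.

## Problem sizes and runtime

The default synthetic experiment (151 × 36 matrix, 32 starts) fits in a few
seconds for two states and under ~15 s for three states on one CPU; the
acceptance script (three noiseless fits plus a 20-seed decomposition study)
completes in well under a minute. Monte-Carlo checks in the test suite use
20 seeds at 12 starts for noisy refits and a 31-wavelength grid for
exhaustive-oracle comparisons; these sizes were chosen as the smallest at
which the checked statistics are stable.

## A worked example

```{r example, eval = FALSE}
library(cdthermo)

# simulate the 40-repeat construct with 1% noise, fit three states
spec <- synthetic_preset("vpgvg40", noise_sigma = 0.01, scattering = FALSE)
series <- generate_series(spec)
fit <- fit_global(series, n_species = 3)
tidy(fit)
glance(fit)
autoplot(fit)

# scattering basis via the Kramers-Kronig chain, then decompose the
# infinite-temperature extrapolation of the fit
bm <- default_band_models()[c("disordered", "beta_turn")]
scatter <- scattering_basis_set(bm, fit$wavelengths)
obs <- extrapolate_spectrum(fit, "infinite")
dec <- decompose_suspension_spectrum(obs, make_basis_spectra(bm, fit$wavelengths)$cd,
                                     scatter)
structure_ratio(dec, "absorbance")
```
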