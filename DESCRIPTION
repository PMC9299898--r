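Package: cdthermo
Title: Thermodynamic Global Fitting of Temperature-Resolved Circular Dichroism Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing temperature series of circular dichroism (CD)
    spectra of thermoresponsive polypeptides such as elastin-like proteins.
    Implements matrix least-squares global fitting of a Boltzmann population
    model (two or three conformational species with temperature-independent
    transition enthalpies and entropies), resolving pure-species spectra by
    variable projection; a maximum-a-posteriori variant with scattering-based
    spectrum weights and reference-shape priors for phase-separating samples;
    Kramers-Kronig transformation of absorptivity spectra into refractive-index
    gradients and construction of differential-scattering basis spectra; and
    decomposition of above-transition suspension spectra into difference-
    absorbance and differential-scattering portions with disordered:beta-turn
    coefficient ratios. A synthetic-data generator produces temperature series
    with the statistical structure the analysis assumes, so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
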