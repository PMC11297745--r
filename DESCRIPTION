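Package: rootEIT
Title: Spectral Electrical Impedance Tomography of Plant Root Systems in Rhizotrons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spectral electrical impedance tomography
    (sEIT) root phenotyping in a water-filled rhizotron. Provides
    model-resolution-matrix based optimization of four-point measurement
    schemes under an injection-dipole budget, a complex-conductivity
    finite-element forward solver with adjoint sensitivities, regularized
    Gauss-Newton tomographic inversion of impedance magnitude and phase,
    per-cell Debye decomposition of complex resistivity spectra into total
    chargeability and mean relaxation time, and estimation of root biomass
    and surface area from the integrated root-zone chargeability via
    power-law calibrations. Includes synthetic phantom and plant-ensemble
    generators so the full workflow can be exercised and validated without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
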