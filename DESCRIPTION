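Package: vpmc
Title: Virtual-Particle Monte Carlo Proton Dose Engine with Aperture-Block
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo dose calculation for pencil beam scanning proton
    therapy with patient-specific brass aperture blocks, as used in
    proton-based stereotactic radiosurgery. Provides analytic and
    history-fitted physics tables (Bethe stopping power, Bohr straggling,
    Highland multiple scattering, a simplified nuclear removal model), a
    conventional condensed-history reference engine, a virtual-particle
    engine in which every particle is initialized before transport and
    advanced by a single table-driven update rule, crossing-number
    aperture-opening geometry, 3D gamma analysis, dose-volume plan indices,
    and scenario-based worst-case robust optimization of spot weights.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    grDevices,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
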