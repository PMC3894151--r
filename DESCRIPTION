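Package: gpconf
Title: Gaussian Process Surrogate Models for Conformational Energies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns the conformational energy surface of a single flexible
    molecule from reference quantum-chemical calculations by Gaussian process
    regression on an inverse-distance/nuclear-charge (Coulomb matrix)
    representation.  The model's predictive variance gates which new
    conformations can be predicted cheaply and which must be recomputed by the
    expensive reference method ("learning on the fly").  Includes
    energy-stratified nested cross-validation with noise-level selection,
    y-randomization validation, ROESY/NOE distance-constraint compliance
    scoring with methyl averaging, PCA projections with Nadaraya-Watson
    smoothed energy landscapes, and a seeded synthetic conformer generator
    with an analytic energy oracle for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
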