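Package: bdbmicro
Title: Background-Deflection Brillouin Microscopy Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward optical simulation of a single-stage VIPA (virtually
    imaged phased array) Brillouin spectrometer with pupil diffraction masks,
    together with the full Brillouin spectral-analysis chain: synthetic
    spectrum and cell-phantom generation, pixel-to-frequency calibration,
    Lorentzian peak fitting with uncertainties, 3D Brillouin map
    reconstruction, and compartment-level biomechanical statistics
    (longitudinal modulus conversions, fixed-to-living q ratios, group
    comparisons). Includes closed-form Fraunhofer kernels for circular,
    rectangular and rhomboidal apertures, spectral-contrast and
    mask-suppression metrics, and a reproducible end-to-end pipeline driven
    by YAML configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
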