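Package: tubexciton
Title: Exciton Spectra and Self-Assembly Kinetics of Double-Walled Molecular Nanotubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the self-assembly of double-walled cyanine-dye
    nanotubes through polarized absorption spectroscopy. Generates synthetic
    nanotube geometries (2D brickwork lattices rolled into concentric
    cylinders) and stochastic outer-wall recovery trajectories, computes
    disorder-averaged polarized absorption, linear dichroism (LD) and reduced
    LD spectra with a Frenkel exciton model using extended-dipole couplings,
    identifies orientational patches by density-based clustering of
    regularized positions and transition-dipole orientations, and fits
    empirical rate-equation models (immediate versus delayed molecular
    ordering) to OD/LD/LD_r time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
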