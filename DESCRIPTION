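Package: llcchar
Title: Characterisation of Lyotropic Liquid-Crystalline Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Structural and functional characterisation of lipid mesophase
    nanoparticles (cubosomes and hexosomes). Detects Bragg peaks in 1D
    small-angle X-ray scattering profiles, assigns the mesophase space group
    (Pn3m, Im3m, p6mm and others) by spacing-ratio matching, fits lattice
    parameters by linear regression with an intercept quality check, and
    derives water-channel radii. Estimates lattice spacings from periodic
    micrograph-like images via 2D power spectra with Friedel-pair spot
    detection and via real-space line profiles. Computes standard curves,
    dye loading and release efficiencies, and the inner-minus-outer GUV
    fluorescence statistic used to score membrane-fusion payload delivery.
    Ships seeded synthetic-data generators with attached ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
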