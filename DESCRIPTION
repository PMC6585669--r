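Package: wmgre
Title: Susceptibility-Weighted Gradient-Echo Signal Simulation from White-Matter
    Axon Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-dimensional forward simulator of the multi-echo gradient-echo
    (GRE) magnetic-resonance signal arising from white-matter microstructure.
    Generates axon cross-section geometries of increasing realism (nested
    circles and ellipses, random close packings of polydisperse fibers, warped
    and irregular outlines, loaded segmentation rasters), assigns each myelin
    pixel an anisotropic magnetic-susceptibility tensor oriented with the
    radially stacked phospholipid bilayers, computes off-resonance frequency
    maps with a Fourier-domain tensor dipole solver, and predicts the complex
    three-compartment GRE signal (magnitude and unwrapped phase) under static
    or diffusing magnetization, including demyelination sweeps in which the
    myelin sheath is thinned from the inside out.
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
    png,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
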