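Package: foveatopo
Title: Foveal Cone Topography, Retinal Magnification and Fixation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing foveal cone photoreceptor topography and its
    dependence on eye length. Implements a four-surface paraxial schematic eye
    (secondary nodal point and retinal magnification factor), sliding-window
    cone density mapping from labelled cone coordinates in angular and linear
    units, eccentricity and meridional density profiles, preferred-retinal-locus
    and fixation-stability estimation via the bivariate contour ellipse area
    (BCEA), hexagonal-packing Nyquist sampling limits, cohort-level regression
    and power analysis, and a synthetic generator of quasi-hexagonal cone
    mosaics, fixation traces and cohorts under three myopic eye-growth models
    (global expansion, equatorial stretching, over-development).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
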