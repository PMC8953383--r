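Package: spheroidGNP
Title: Gold-Nanoparticle Redistribution Kinetics in 3D Tumor Spheroid Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-based quantification of gold-nanoparticle (GNP)
    redistribution from extracellular matrix (ECM) to 3D tumor nodules grown
    on a Matrigel bed. Provides spheroid segmentation and ellipsoid
    morphometry from darkfield/fluorescence frames, Gompertzian growth-curve
    fitting with doubling-time estimation, lognormal size-mixture analysis of
    nodule populations, control-corrected compartmental intensity kinetics
    with two-phase uptake-slope and plateau detection, clonogenic
    survival-factor and sensitivity-enhancement-ratio (SER) analysis, and a
    seeded synthetic-study generator that emulates the full microscopy and
    clonogenic assay with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mclust,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
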