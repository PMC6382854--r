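Package: mapquant
Title: Quantification of Cortical Microtubule Arrays, Membrane Particles
    and Microtubule-Associated Protein Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image- and track-based quantification of cortical microtubule
    arrays and microtubule-associated protein (MAP) behavior in light and
    electron microscopy. Provides calibrated image/time-lapse containers,
    the imaging primitives the pipelines compose (Gaussian smoothing, Sobel
    gradients, Laplacian-of-Gaussian ridge detection, Otsu thresholding,
    despeckling, component filtering, skeletonization and prominence-based
    maxima finding), and analysis stages for microtubule coverage,
    plasma-membrane particle density with Golgi subtraction, skeleton-based
    fiber-diameter bundling metrics, time-phased image subtraction and
    kymograph velocimetry, mean-squared-displacement diffusion estimation
    for lattice-diffusing molecules, gold-label spacing and row geometry on
    negative-stain TEM transects, Pearson and van Steensel co-localization,
    and small sequence and labeling formulas (Kyte-Doolittle hydropathy,
    substitution-matrix residue classing, degree-of-labeling and mean
    residue ellipticity). Synthetic-data generators with ground-truth
    sidecars allow closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
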