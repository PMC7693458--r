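Package: hexflora
Title: Bee Colour-Vision Modelling and Intrafloral Colour Modularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models floral reflectance spectra through a trichromatic bee
    visual system into the hexagon colour space and analyses intrafloral
    colour organisation. Provides reflectance spectrum input/output and
    resampling, quantum-catch and photoreceptor-excitation computation with
    von Kries adaptation, hexagon chromaticity coordinates, hue, spectral
    purity (via spectrum-locus ray intersection) and chromatic contrast per
    floral patch, among-individual Euclidean and angular colour distances,
    complete-block analyses of variance with false-discovery-rate pairwise
    comparisons, circular statistics (Watson-Williams one-way test and
    Watson's two-sample U2 test), and a permutation-based covariance-ratio
    test of intrafloral colour modularity with bootstrap confidence
    intervals. A seeded generator of synthetic orchid-like reflectance
    datasets with planted modular covariance supports simulation studies
    and the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
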