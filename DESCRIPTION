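Package: slopeCN
Title: Spectral Slope Features for Monitoring Leaf Carbon-to-Nitrogen Ratio
    from Canopy Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the leaf carbon-to-nitrogen ratio (C/N) of
    cereal crops from canopy hyperspectral reflectance (400-1050 nm).
    Implements mean-normalization preprocessing that suppresses illumination
    differences, segment-slope feature extraction from the normalized
    reflectance curve (seven single slopes, six ratios and nine combined
    features anchored on the red-edge slope), a registry of 22 comparison
    vegetation indices including derivative-based red-edge quantities,
    univariate model selection over linear, exponential and logarithmic
    families, exact branch-and-bound best-subset multiple regression, and
    noise-equivalent sensitivity analysis. A parametric canopy-spectrum
    generator makes the full pipeline testable without field data. Spectra
    are stored as a SummarizedExperiment extension.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Spectra, Regression, FeatureExtraction, Agriculture
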