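Package: evraman
Title: Single-Particle Raman Profiling of Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for single-particle Raman
    spectroscopy of extracellular vesicles (EVs). Provides a synthetic
    single-EV spectrum generator (pseudo-Voigt biomolecular bands,
    nonlinear CCD axis, PBS background, shot-like noise, cosmic spikes),
    the full spectral preprocessing chain (cosmic-spike removal, relative
    intensity response correction, background subtraction, asymmetric
    least-squares Whittaker baseline, Savitzky-Golay smoothing, area
    normalization), dimensional reduction array (DRA) heatmaps, PLS
    discriminant analysis with venetian-blinds cross-validation and
    Q-residual/Hotelling T2 outlier exclusion, band-target entropy
    minimization (BTEM) for reference-free recovery of pure biomolecular
    spectra, and convex-mixing (non-negative sum-to-one least squares)
    compositional abundance estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    optparse,
    png,
    pROC,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
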