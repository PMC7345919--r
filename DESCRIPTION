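Package: nmrfp
Title: Serum 1H NMR Metabolomic Fingerprinting by Orthogonal Partial
    Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of untargeted 1H NMR serum
    metabolomics studies of energy-balance biomarkers in early-lactation
    dairy cows. Generates synthetic serum-like spectra with known ground
    truth (Lorentzian multiplets, peak jitter, baseline drift, noise),
    preprocesses them (region deletion, correlation optimized warping,
    total-area normalization, asymmetric least squares baseline
    correction, mean centering), fits single-response OPLS regression
    models of beta-hydroxybutyrate and non-esterified fatty acid
    concentrations on spectra, scores variables by VIP, validates models
    by venetian-blind cross-validation, external validation and
    y-permutation testing, screens samples by PCA with Hotelling ellipse
    flags, partitions spectral variance over design factors by ASCA, and
    derives VIP-based metabolomic fingerprints with STOCSY peak grouping
    and a four-way biomarker classification of metabolites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
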